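Package: lungdect
Title: Dual-Energy CT Lung Aeration Analysis and Dynamic Single-Slice
    Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of dual-energy computed tomography (DECT)
    of the ventilated lung. Performs per-voxel three-material differentiation
    of co-registered low/high-energy volumes into gas, soft tissue and
    iodinated blood fractions with ROI-based coefficient calibration;
    classifies lung parenchyma into aeration compartments (atelectasis, poor,
    normal, overdistension) from the gas volume fraction; classifies dynamic
    single-slice CT frames as inspiratory or expiratory from per-frame gas
    volume; builds normalized density and material-fraction histograms;
    compares dynamic-slice against whole-lung summaries with correlation,
    Bland-Altman limits of agreement and phase-resolved bias; and summarizes
    cranio-caudal displacement fields over gravitational regions. A synthetic
    thorax phantom with known ground truth drives testing and demonstration
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
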