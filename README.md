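# lungdect

Quantitative analysis of dual-energy CT (DECT) of the ventilated lung, with
a focus on how well a **dynamic single-slice CT (dCT)** series — a fixed
thin slab imaged at 1 Hz while the lung moves during tidal ventilation —
represents the **whole lung**.

The package is aimed at researchers doing quantitative CT of experimental
lung injury (ARDS models, ventilator-induced lung injury), where dCT is the
standard way to resolve intra-tidal changes in aeration and atelectasis but
is blind to everything outside its field of view.

## What it computes

**Three-material differentiation.** The same anatomy imaged at two X-ray
energies gives two HU values per voxel. With DECT coefficients
C<sub>m,e</sub> (the CT density equivalent to 100 % of material *m* at
energy *e*), the volume fractions *f* of gas, soft tissue and iodinated
blood solve, per voxel,

```
HU_low  = f_gas C_gas,low  + f_tis C_tis,low  + f_bld C_bld,low
HU_high = f_gas C_gas,high + f_tis C_tis,high + f_bld C_bld,high
1       = f_gas + f_tis + f_bld
```

Coefficients are calibrated from anatomical ROIs: mean density of the
descending thoracic aorta for iodinated blood, mean density of the
parasternal musculature for soft tissue, and a fixed −1000 HU at both
energies for gas. Out-of-simplex solutions (possible under noise) are
clipped at zero and renormalized, with the projection distance stored as a
per-voxel diagnostic.

**Aeration compartments.** Lung voxels are classified by gas volume
fraction: atelectasis (< 10 %), poor aeration (10–50 %), normal aeration
(50–90 %), overdistension (> 90 %) — on a non-contrast scan with soft
tissue at 0 HU these cutoffs are the familiar −100 / −500 / −900 HU
thresholds. Classifying the gas-fraction image instead of contrast-enhanced
HU avoids iodine inflating the atelectatic fraction.

**Tidal frame classification.** Each dCT frame's gas volume is the slab
volume times its mean gas fraction; frames within 30 % of the min-to-max
range from the minimum are expiratory, within 30 % of the maximum
inspiratory, and mid-cycle frames are excluded.

**Agreement statistics.** Eight variables of interest (mean merged CT
density; volume fractions of soft tissue, gas, iodinated blood; the four
aeration compartments) are compared between dCT and whole lung with
correlation (r²), Bland–Altman mean difference and 95 % limits of agreement
(mean ± 1.96 SD) with confidence intervals, phase-resolved (inspiratory vs
expiratory) bias, and the per-mm effect of cranio-caudal slice position.
Density and fraction distributions are compared as normalized fixed-bin
histograms (10-HU bins over −1000…+500 HU; 1 % bins over 0…100 %) via
Pearson correlation.

**Displacement analysis.** A dense expiration→inspiration displacement
field (consumed from an external B-spline registration, or simulated) is
summarized over 12 equal-height gravitational regions of the selected
slice, plus the fractions of the slice moving < 5, 5–10 and 10–15 mm
caudally.

**Synthetic thorax phantom.** Every stage is testable without scanner data:
`generatePhantom()` builds a supine thorax with a gravitational aeration
gradient, iodinated vessels, dependent atelectasis, a raised-cosine tidal
waveform and a smooth mid-lung-weighted displacement field — all with known
ground truth and fully seeded.

## Worked example

```r
library(lungdect)

spec  <- PhantomSpec(seed = 7)            # 48 x 64 x 16 voxels, 0.5 x 0.5 x 5 mm
truth <- generatePhantom(spec)
pair  <- renderDect(truth, defaultMaterialBasis())   # forward model + HU noise
basis <- calibrateBasis(pair, truth@aortaMask, truth@muscleMask)
basis
#> MaterialBasis (HU per 100% material):
#>                      low     high
#> gas             -1000.00 -1000.00
#> soft_tissue        60.25    39.88
#> iodinated_blood   399.92   249.76
#>   system condition number 1.73e+03

fractions <- decomposeDect(pair, basis, truth@lungMask)
labels    <- classifyAeration(fractions)
round(summarizeVariables(mergeVolumes(pair), fractions, labels), 1)
#>       ct_density_hu      fv_soft_tissue              fv_gas  fv_iodinated_blood
#>              -482.4                45.9                49.9                 4.2
#>      fv_atelectasis   fv_poorly_aerated fv_normally_aerated    fv_overdistended
#>                11.8                32.2                56.1                 0.0
```

The calibrated coefficients recover the rendering basis to well under 1 HU,
and the decomposed whole lung is about half gas with a dependent
atelectatic compartment of ~12 % — the composition the phantom was built
with. The eight values are the "variables of interest" used in all
agreement analyses; material fractions and compartment fractions each sum
to 100 %.

```r
td <- simulateTidalSeries(spec)
head(classifyFrames(td$series), 5)
#>   frame time_s gas_volume_ml      phase
#> 1     1      0      1.035864 expiratory
#> 2     2      1      1.046602 expiratory
#> 3     3      2      1.077179 expiratory
#> 4     4      3      1.122942   excluded
#> 5     5      4      1.176922   excluded

cc <- ccDisplacementSlice(truth@field, truth@sliceMask)
round(regionalMeans(cc, truth@sliceMask), 2)
#>  [1] 1.40 2.88 4.92 6.85 8.39 9.15 9.10 8.22 6.63 4.63 2.71 1.25
round(movementFractions(cc, truth@sliceMask), 3)
#>   lt_5mm  mm_5_10 mm_10_15  gt_15mm
#>    0.327    0.673    0.000    0.000
```

Frames track the raised-cosine gas waveform (expiratory at the trough,
excluded mid-cycle); the regional caudal displacement peaks in the
mid-gravitational lung and about a third of the slice stays within one
5-mm slice thickness.

`runPipeline(pipelineConfig(outDir = "run"))` chains all stages over a grid
of simulated ventilatory conditions and writes the CSV/NIfTI report bundle
(variables, frames, histograms, Bland–Altman tables, phase bias,
slice-position regression, displacement summaries) plus a `manifest.json`;
a thin command-line wrapper is at `inst/scripts/run-pipeline.R`.

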