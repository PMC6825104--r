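---
title: "Dual-energy CT lung analysis with lungdect: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy CT lung analysis with lungdect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdect)
```

# The problem

Dynamic single-slice CT (dCT) images a fixed thin slab of the thorax at
around 1 Hz while the lung ventilates, resolving intra-tidal changes in
aeration that whole-lung scans acquired during apnoeas cannot show. Two
questions follow: whether the slab is compositionally representative of the
whole lung, and how much of the slab physically leaves the field of view
with inspiration. lungdect implements the quantitative machinery for both
questions — dual-energy three-material differentiation, aeration
compartmentalization, tidal frame classification, distribution and
agreement statistics, and regional displacement summaries — together with a
fully seeded synthetic thorax phantom so that every stage can be verified
against known ground truth.

# The three-material model

A dual-energy acquisition provides two HU values per voxel. With the DECT
coefficient matrix $C_{m,e}$ (the density of 100 % of material $m$ at
energy $e$), the gas, soft-tissue and iodinated-blood volume fractions
solve the voxelwise $3 \times 3$ system

$$\mathrm{HU}_e = \sum_m f_m C_{m,e} \;(e \in \{\mathrm{low},
\mathrm{high}\}), \qquad \sum_m f_m = 1 .$$

Assumptions worth stating: attenuation mixes linearly (no beam hardening or
scatter modelling), exactly three materials span each voxel, and the
coefficients are spatially constant. The system matrix is voxel-independent,
so `decomposeDect()` applies one shared inverse to all voxels — a numerical
convenience; the contract is the mathematical solution.

**Calibration.** `calibrateBasis()` takes the per-energy mean HU of a
descending-aorta ROI (iodinated blood) and a parasternal-muscle ROI (soft
tissue), with gas fixed at −1000 HU at both energies. Identifiability
requires that blood and tissue separate across energies; we enforce a hard
condition-number threshold of $10^6$ on the $3\times3$ system and name the
nearly indistinguishable material pair in the error, preferring a loud
failure to silent noise amplification.

**Simplex projection.** Under HU noise, raw solutions can leave the unit
simplex. Negative fractions are clipped to zero and the remainder
renormalized to sum to one. This preserves the $\sum f = 1$ contract that
segmentation and summary statistics rely on, at the cost of a small bias
near the simplex boundary; the Euclidean projection distance is stored per
voxel so heavy projection is auditable, and `project = FALSE` exposes the
raw (linear, unbiased) estimator for diagnostics. The unbiasedness of the
raw estimator under Gaussian HU noise is checked by the test suite at
$10^5$ voxels and 10 HU noise.

**Merge volume.** The display/segmentation image is the voxelwise blend
$w \cdot \mathrm{HU}_{high} + (1-w)\,\mathrm{HU}_{low}$ with $w = 0.7$ by
default. Which energy carries the 70 % is a genuine free choice; we default
to the high-energy image, matching conventional mixed-image practice, and
expose `weightHigh` so the swap is one argument.

# Aeration compartments

Lung voxels are classified on the gas volume fraction — not on
contrast-enhanced HU, where iodine masquerades as tissue and inflates the
atelectatic fraction. Cutoffs are 0.10 / 0.50 / 0.90; on a non-contrast
scan with soft tissue at 0 HU these correspond to −100 / −500 / −900 HU
(`noncontrastEquivalentHU()`). The conventional printed ranges overlap at
their boundaries ("10–50 %", "50–90 %"), so a deterministic convention is
fixed: half-open intervals $[0, 0.10) \to$ atelectasis, $[0.10, 0.50) \to$
poor, $[0.50, 0.90] \to$ normal, $(0.90, 1] \to$ overdistended. The choice
is arbitrary at measure-zero boundaries; what matters is that it is single
and documented, and the monotonicity property (raising gas fractions never
demotes a voxel to a less-aerated class) holds by construction.

# Tidal frame classification

Each frame's gas volume is the slab volume times its mean gas fraction.
Frames "within 30 % of the minimum or maximum value" are expiratory or
inspiratory respectively. We read the 30 % against the min-to-max *range*
measured from each extreme: with $R = g_{max} - g_{min}$, a frame is
expiratory when $g \le g_{min} + 0.3R$ and inspiratory when
$g \ge g_{max} - 0.3R$. The alternative reading (±30 % of the raw value) is
unit- and offset-dependent — adding a constant to all gas volumes would
change the labels, and for small relative excursions it labels every frame.
The range reading is offset- and scale-invariant (both properties are
tested) and excludes mid-cycle frames as observed in practice. Extremes are
taken over the whole condition recording, not per breath. A series with no
tidal variation ($R = 0$) is rejected as degenerate rather than labelled
arbitrarily, and `band` $\ge 0.5$ is rejected because the two sets would
overlap.

# Distributions

Histograms use fixed bins — 10-HU bins on $[-1000, 500]$ (150 bins) for
merged CT density, 1 % bins on $[0, 100]$ % for material fractions — with
left-closed right-open bins and a closed last bin, normalized to sum to 1
so differently sized volumes compare. Masked voxels outside the HU range
(dense contrast, metal) are *excluded and counted*, not clamped: clamping
would silently distort the edge bins. Pearson correlation between two
histograms is computed over all bins, shared zeros included, as a fixed-bin
design implies; a histogram with zero variance across bins has no defined
correlation and is rejected.

# Agreement statistics

Eight variables summarize each imaging context: mean merged CT density and
the volume fractions (%) of soft tissue, gas, iodinated blood, atelectasis,
poor, normal and overdistended aeration. Fraction statistics are computed
on the percentage scale, as conventionally printed.

`blandAltman()` reports the mean dCT − whole-lung difference and 95 %
limits of agreement $\bar d \pm 1.96\,\mathrm{SD}(d)$, using the literal
1.96 multiplier of the classical method at 95 % (the exact normal quantile
otherwise). Confidence intervals use the $t$ quantile on $n-1$ df with
$\mathrm{SE}(\bar d) = \mathrm{SD}/\sqrt{n}$ for the mean and the classical
large-sample $\mathrm{SE} = \mathrm{SD}\sqrt{3/n}$ for each limit — the
standard Bland–Altman formulas, stated here because published tables rarely
say which SE they used. The paired $t$ test is two-sided and per-variable;
no multiplicity correction is applied, matching how such tables are
reported. Phase-resolved bias (`phaseBias()`) gives per-phase mean (SD) and
the paired inspiratory − expiratory difference with ±1.96 SD limits.
`slicePositionRegression()` pools per-slice variable values expressed
relative to the most caudal slice and fits ordinary least squares against
cranial distance in mm.

# Displacement analysis

Image registration is consumed, not performed: the input is a dense
expiration→inspiration displacement field in mm (4-D NIfTI or simulated),
with component 3 cranio-caudal and positive = caudal. The selected slice's
lung mask is divided into 12 equal-height bands along the gravitational
(anterior→posterior) axis, measured over the *lung mask's* bounding extent
— the bands in published figures hug the lung, not the image frame — with
empty bands near the mask's apex reported as missing. Band membership is
decided in exact integer arithmetic (smallest $k$ with
$(j - j_{min} + \tfrac12)/(j_{max} - j_{min} + 1) \le k/n$) so voxels whose
centres land exactly on a band boundary are assigned identically on every
platform. Movement fractions bin caudal displacement at one, two and three
slice thicknesses (< 5, 5–10, 10–15 mm); cranial (negative) movement counts
in the first bin, since displacements beyond 5 mm cranially do not occur at
the studied level, and anything beyond 15 mm is reported separately rather
than silently absorbed. Group summaries use the median and IQR with R's
default linear interpolation between order statistics (quantile type 7).

# The synthetic phantom

`PhantomSpec()` defines a miniature supine thorax; its defaults are the
reference study conditions used throughout the tests and the demonstration
pipeline:

* **Grid** 48 × 64 × 16 voxels at 0.5 × 0.5 × 5 mm — the 5-mm slice
  thickness of thin-slab dCT, an in-plane resolution typical of
  reconstructed CT, and a grid small enough that the full suite runs in
  seconds. The phantom is a *miniature*: geometric plausibility, not
  anatomical scale, is the goal.
* **Aeration gradient** from 0.85 (anterior) to 0.25 (posterior) gas
  fraction: a supine gravitational gradient spanning normal aeration down
  to poor aeration, with voxelwise jitter (SD 0.01, truncated at 3 SD so
  the gradient ordering survives).
* **Dependent atelectasis**: the most posterior 15 % of the lung extent at
  gas fraction 0.03, well under the 0.10 cutoff.
* **Vessels**: six cranio-caudal cylinders of radius 1.5 voxels at 80 %
  iodinated blood, giving the characteristic bimodal density distribution
  of contrast-enhanced lungs.
* **HU noise** 5 HU per energy by default (10 HU in the noise-robustness
  tests): scanner noise levels are acquisition-dependent and the value is
  configurable, not calibrated.
* **Tidal waveform**: a raised cosine between end-expiration and
  end-inspiration — smooth, symmetric, and it reaches its extremes exactly,
  so trough/peak frames are unambiguous. Modulated voxels recruit a
  fraction `tidalAmplitude` (default 0.3) of their non-gas space at
  end-inspiration, which keeps fractions on the simplex by construction.
  16 frames per cycle × 2 cycles at 1 Hz.
* **Displacement field**: caudal displacement sampled on a 3-mm
  control-point grid and interpolated trilinearly to the voxel grid,
  peaking mid-gravitationally as $\mathrm{peak} \cdot \sin^2(\pi y)$ with a
  small multiplicative control-point jitter in $[0.9, 1]$, so the caudal
  component never exceeds the configured peak (10 mm default). A "uniform"
  profile exists for exactness checks, since any linear interpolant must
  reproduce a constant field.

What the phantom deliberately does **not** emulate: X-ray physics (beam
hardening, scatter, reconstruction kernels — the forward model is linear
mixing plus Gaussian HU noise), cardiac motion, airway trees, lobar
anatomy, registration error (the displacement field is consumed as truth),
and breath-to-breath variability. Passing tests therefore demonstrate that
the *algorithms* are correct against their mathematical definitions and
self-consistent end to end — not that the acquisition-physics assumptions
hold on any particular scanner.

# Numerical choices, collected

* Degenerate basis: condition number $\ge 10^6$ is an error naming the
  closest material pair.
* Out-of-simplex fractions: clip at 0, renormalize, store the projection
  distance; raw solutions available via `project = FALSE`.
* Aeration boundaries: 0.10 → poor, 0.50 and 0.90 → normal.
* Frame rule: range-referenced band, whole-recording extremes, degenerate
  series rejected.
* Histogram edges: left-closed, last bin closed; out-of-range counted, not
  clamped.
* Bland–Altman: 1.96 multiplier at 95 %; LoA CIs via
  $\mathrm{SD}\sqrt{3/n}$; difference sign is dCT − whole lung.
* Gravitational bands: lung-mask extent, integer-arithmetic boundary
  assignment, empty bands are NA.
* Quantiles: linear interpolation between order statistics.
* Determinism: every generator consumes an explicit seed; derived seeds are
  fixed offsets of the spec/config seed.

# Problem sizes

The test suite exercises the decomposition round trip at $10^6$ voxels
(noise-free, max error below $10^{-9}$) and $10^5$ voxels for the noise
unbiasedness check; frame classification against a brute-force oracle on
1000 random series of 2–60 frames; Bland–Altman recovery at $n = 96$ paired
conditions (the size of a 12-condition × 8-subject study), with the limits
of agreement averaged over 500 replicates because a single $n = 96$ sample
determines each limit only to a sampling SD of about $0.17\sigma$; and the
end-to-end null experiment — a synthetic dCT slab holding exactly the
whole lung's voxel composition, so that all eight mean differences must
vanish within noise — at 12 conditions on a 24 × 32 × 6 phantom. The
demonstration pipeline runs three to four conditions on reduced grids.
These sizes keep the whole suite around ten seconds while leaving each
statistical check with comfortable power.

# Known limitations

* The decomposition assumes exactly three materials; fat and bone bases,
  and projection-domain decomposition, are out of scope.
* Anatomical exclusion of mediastinal structures on real scans is a
  user-supplied mask; no automatic organ segmentation is provided.
* The phase-bias and agreement machinery treats conditions as exchangeable
  paired observations; mixed-effects modelling of PEEP/VT/injury structure
  is out of scope.
* Real dCT frames share one anatomical slab only nominally — through-plane
  motion changes the imaged anatomy. The phantom reproduces the
  *composition* consequences (via the displacement summaries and
  slice-position regression) but not the image-formation consequences.
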