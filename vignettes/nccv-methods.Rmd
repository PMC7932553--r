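---
title: "Quantifying intradermal cystine crystals from RCM Z-stacks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intradermal cystine crystals from RCM Z-stacks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(nccv)
```

## The measurement problem

Cystinosis is a lysosomal storage disorder in which cystine crystallizes
in tissues, including the dermis.  Reflectance confocal microscopy (RCM)
images skin non-invasively as a Z-stack of en-face slices: crystals
appear as small, very bright objects, most densely in the papillary
dermis.  Two things confound a naive bright-object count:

* **dermal papillae** — large bright ring-like structures that produce
  false-positive bright objects, and
* **superficial epidermal speckle** — unspecific bright dots above the
  papillary dermis, present in healthy skin too.

The pipeline addresses both: per slice it (1) detects all small bright
objects, (2) detects skin structure (papillae), (3) removes candidates
overlapping structure, leaving *isolated crystals*; across slices it
restricts 3D quantification to a fixed papillary-dermis band and
summarizes each stack as a single **normalized confocal crystal volume
(nCCV, µm³)**.

## Coordinate and depth conventions

A stack is `H × W` pixels by `n_slices` slices (third array axis, in
acquisition order).  Slices are numbered from 1 and depth is
`depth = index × step_um`: the first slice lies one axial step below the
contact surface.  With the standard 2.8 µm step this places slice 15 at
42 µm and slice 50 at 140 µm — the depth range quantified in 3D.  This
is the only affine indexing convention consistent with both anchor
depths, which is why it is fixed rather than configurable.

The standard acquisition is 78 slices over a 750 µm × 750 µm field.
The lateral field is read as a 750 µm square; pixel size is never stored
in the TIFF, so the sidecar carries it and a missing sidecar falls back
to 0.5 µm/px with a warning.  That fallback is an assumption about the
instrument, flagged as such, not a measured value.

## Segmentation

**Crystal candidates.**  Each slice is background-flattened with a white
top-hat whose disc radius equals the upper crystal size scale
(`sqrt(crystal_area_max_um2 / π)` ≈ 6.9 µm), then thresholded at
`median + bright_z_min × scale`, where the scale is a robust per-slice
noise estimate: the MAD of horizontal first differences divided by √2.
Two numerical points are deliberate:

* the noise scale comes from the *raw* slice, not the top-hat residual,
  whose compressed bulk understates the tail spread; and
* first differences are used instead of the plain slice MAD because
  plateau-like bright structures (papillae) inflate a global MAD while
  their edges contribute almost nothing to first differences.

Components (8-connected in-plane) are kept iff their area lies in
`[crystal_area_min_um2, crystal_area_max_um2]` = [1, 150] µm².  Because
the median/MAD pair is equivariant under gain and offset, detection is
invariant to affine intensity rescaling — important since RCM gain
varies between sessions.

`bright_z_min` defaults to 5.5.  The defaults are calibrated on the
bundled simulator (the reference workflow's own cut-offs live in an
unpublished commercial-tool macro): on crystal-free noise stacks a
threshold of 4 admits roughly two single-pixel false positives per slice
— the 1 µm² area floor cannot reject single pixels at coarse pixel sizes
— while 5.5 is the smallest scanned level with zero false detections
across seeds, and band-depth crystals still sit ~10 noise SDs above
background.  All thresholds remain configuration
(`segmentation_params()`), not constants.

A **rim-artifact guard** handles bright objects *larger* than the
crystal maximum: the top-hat leaves thin bright crescents at their
boundaries which would otherwise pass the area gate.  Bright raw-slice
regions above the crystal maximum veto any candidate within 2 px of
their footprint.

**Skin structure.**  The slice is Gaussian-smoothed at
`structure_smooth_sigma_um` (5 µm), thresholded by Otsu's method,
morphologically closed, hole-filled (so annular papilla rims become
filled footprints — cheaper and more robust than a closing brush large
enough to bridge a ~40 µm lumen), and components of at least
`structure_area_min_um2` (500 µm²) are kept.  Otsu always returns a
split, even on a noise-only slice where it would mark half the field as
"structure"; a slice is therefore treated as structure-free unless the
above/below-threshold class means differ by at least four times the
robust spread of the lower class.  The factor 4 rejects unimodal noise
(whose class separation is ≈1.6 smoothed-noise SDs) with a comfortable
margin while accepting genuinely bimodal slices, including the
adversarial case of structure covering half the field.

**Exclusion.**  Under the default `any_pixel` rule a candidate is
removed iff any of its pixels lies in any structure region
(`centroid_inside` and `fraction ≥ f` are selectable alternatives; the
reference workflow states overlap-based elimination without a
fraction).  Survivors are relabelled contiguously with areas unchanged.

## Profiles, 3D reconstruction, and nCCV

Per slice, `crystal_area_um2` is the summed isolated-crystal area and
`analyzed_area_um2` the field area minus structure area; their ratio is
the **normalized crystal area** plotted against depth.  Structure area
is subtracted in 2D as well as 3D for consistency (the 2D convention is
not stated in the reference description; this keeps the two views of
the same masks proportional).

Within the band (default slices 15–50, configurable per stack), the
per-slice isolated-crystal masks are stacked and labelled with
**26-connectivity**: the axial step (2.8 µm) exceeds the pixel size, so
conservative diagonal linking avoids fragmenting one crystal across
slices.  Anisotropy enters only the volume computation
(`voxels × pixel² × step`).

The normalization convention is isolated in `compute_nccv()`.  Writing
\(V_c\) for summed crystal volume, \(V_a\) for analyzed volume (band
gross volume minus structure volume) and \(V_{ref}\) for the nominal
reference volume (reference field² × band slice count × step):

\[ \mathrm{nCCV} = V_c \cdot \frac{V_{ref}}{V_a} \quad [\mu m^3] \]

The printed unit of the statistic is µm³ and the exact normalization in
the original macro-based workflow is not published; among the conventions compatible
with a µm³ result we chose the one that (a) reduces to the raw crystal
volume on a standard structure-free acquisition, (b) corrects stacks
with more structure upward so equal true burdens score equally, and
(c) makes laterally cropped fields comparable to full ones — which the
test suite exploits by simulating small fields.  Two invariants follow
by construction and are tested: 2D/3D consistency
(\(\sum_k A_k \cdot \mathrm{step} = V_c\) exactly, both computed from
the same masks) and additivity over disjoint crystal sets.

`compute_nccv()` returns a classed S3 object with `print`, `summary`,
`plot` and `as.data.frame` methods:

```{r example, eval = FALSE}
g <- acquisition_geometry(pixel_size_um = 1, field_um = 160)
sim <- simulate_stack(sim_config(geometry = g, n_crystals = 40, seed = 11))
r <- compute_nccv(sim$stack)
summary(r)
plot(r)
```

## The simulator

`simulate_stack()` generates stacks with exact voxel ground truth; it
is the package's oracle, and every acceptance-level property is judged
against it.  It emulates, in order: papillae as bright annular rims
(8 µm wall, 30 µm footprint radius, spanning the band depths) whose
filled footprints form the structure mask; crystals as hard-edged
voxelized ellipsoids (spherical-equivalent radius ~ N(1.5, 0.5²) µm,
truncated at 0.9 µm so each crystal owns at least one voxel) placed
with a unimodal depth profile supported on slices 15–50; a configurable
fraction (default 0.2) planted *inside* papillae as confounders;
occasional epidermal speckle (default 2 × 10⁻⁵ µm⁻² per slice) confined
to slices above the band; then exponential depth attenuation
(0.004 µm⁻¹) and additive Gaussian noise (SD 0.03 on a [0, 1] intensity
scale), applied after ground truth is recorded.  Output is quantized to
the 16-bit grid so TIFF round trips are bit-exact.

Design notes:

* **Pixel size 1 µm/px by default.**  The instrument's pixel size is
  not published; 1 µm/px keeps 1.5 µm crystals resolvable at 2–3 px
  while keeping full-field stacks tractable.  The sidecar fallback for
  *real* data stays at the finer 0.5 µm/px assumption.
* **Ellipsoids, not irregular crystal shapes.**  Ground-truth volume
  must be exact and the pipeline uses no shape prior, so shape realism
  buys nothing for validation.
* **Cohort loads are moment-matched lognormals** with group targets
  1934.0 [SD 1169.1] µm³ (patients) vs 363.1 [194.3] µm³ (controls),
  planted to target by accumulation.  A normal model truncated at zero
  was considered and rejected: with these moments it caps the
  achievable group AUC near 0.95, inconsistent with the ~0.98
  discrimination reported for real cohorts, whereas the lognormal — the
  natural model for a positive right-skewed burden — reproduces it and
  needs no truncation.
* **What is not modelled:** RCM speckle statistics and optical
  point-spread, collagen texture, motion between slices, melanin
  background (highly pigmented skin is an exclusion criterion for the
  assay, not something the pipeline corrects).  Passing tests therefore
  demonstrate correctness of the measurement machinery under controlled
  confounds, not robustness to every property of clinical images.

## Statistics layer

* **Per-slice group comparison**: per-slice two-sample Welch tests with
  Šidák familywise control, `α' = 1 − (1 − α)^{1/m}`.  A literal
  two-factor repeated-measures decomposition was not used because the
  target quantity is the per-slice mean difference and the factorial
  structure is unspecified; the Šidák-adjusted per-slice test controls
  the familywise error for exactly that question.
* **Group comparison of nCCV**: Welch by default (patient and control
  spreads differ severalfold; the pooled form is an option).
* **ROC/AUC**: Mann–Whitney with ties counted ½, confidence intervals
  by seeded stratified percentile bootstrap (2000 resamples), a
  distribution-free choice that makes no normality assumption about the
  AUC sampling distribution.
* **Associations**: logistic (binary) or OLS (continuous) with z-scored
  nCCV as the main predictor; effects per 1 SD with Wald 95% CI and
  chi-square.  CKD stage is modelled linearly (an ordinal model would
  also fit; the printed effect is a slope, so OLS matches the reported
  estimand).  Quasi-separation is flagged with a warning rather than
  returned silently.  Missing clinical fields are handled by listwise
  deletion per model with the analyzed n reported; no multiplicity
  correction is applied across outcomes, matching the reference
  analysis.
* **Helpers**: repeatability CV (100 × SD/mean, n−1 denominator),
  granulocyte cystine = 1.95 × leukocyte cystine, and bedside Schwartz
  eGFR = 0.413 × height/creatinine (the constant comes from the cited
  Schwartz reference).

## Problem sizes used by the test suite

Simulated acquisitions always keep the standard axial geometry (78
slices, 2.8 µm step) so the band convention is exercised as-is; lateral
fields are cropped to keep runtimes proportionate, which nCCV's
reference normalization makes legitimate: 256 µm for volume-recovery
checks (20 stacks), 160 µm for recall/precision, discrimination (25+25
subjects) and repeatability (10 fields × 3 re-acquisitions), and 112 µm
for the per-slice band-defense cohorts (10 runs × 30 subjects).  These
sizes are the package's chosen trade-off between Monte-Carlo stability
and turnaround.

## Known limitations

* Segmentation thresholds are simulator-calibrated defaults; real
  acquisitions need a calibration pass (they are all exposed in
  `segmentation_params()` and the CLI).
* The epidermis/dermis boundary is a fixed band, not auto-detected; a
  stack acquired with unusual contact pressure would need a per-stack
  band override.
* Structure detection assumes papillae are the dominant smooth bright
  structure; vessels or glands of comparable scale would be excluded as
  structure too (conservative for crystal quantification).
* nCCV values are comparable only under a shared reference geometry;
  the reference is recorded in every result object.
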