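# nccv — intradermal cystine crystal quantification from RCM Z-stacks

Cystinosis patients accumulate cystine crystals in the dermis, and the
crystal burden tracks long-term disease status.  Reflectance confocal
microscopy (RCM) images the skin non-invasively as a Z-stack of en-face
slices in which crystals appear as small, very bright objects.  This
package turns such stacks into a per-subject biomarker — the
**normalized confocal crystal volume (nCCV, µm³)** — and provides the
statistics used around it, for image-analysis and clinical-research
groups working with intradermal RCM.

The pipeline, per stack:

1. **Detect** all small bright objects per slice: white top-hat
   background flattening, then a robust threshold
   `median + z · MAD-based noise scale` (gain-invariant), 8-connected
   labelling, and area gates (1–150 µm²).
2. **Detect skin structure** (dermal papillae): Gaussian smoothing,
   Otsu threshold with a bimodality guard, closing and hole filling,
   area gate ≥ 500 µm².
3. **Exclude** candidates overlapping structure → *isolated crystals*.
4. **Profile** normalized crystal area (crystal area / analyzed area)
   versus depth, with depth = slice × 2.8 µm (slices 15–50 ↦ 42–140 µm,
   the papillary dermis).
5. **Reconstruct in 3D** within the band (26-connectivity) and compute

   nCCV = V_crystal × V_ref / V_analyzed  [µm³],

   where V_analyzed is the band volume minus structure and V_ref the
   nominal reference volume, so a standard structure-free stack scores
   its raw crystal volume and structure-rich stacks are corrected
   upward.

A synthetic-stack simulator with exact voxel ground truth (planted
crystals, papillae, in-structure confounders, epidermal speckle, depth
attenuation, noise) makes every stage testable without patient data,
and a statistics layer covers the surrounding analyses: per-slice
patient/control comparison with Šidák familywise control, Welch t-test,
ROC/AUC (Mann–Whitney, bootstrap CI), standardized-nCCV regression
associations, repeatability CV, and clinical unit helpers (granulocyte
cystine = 1.95 × leukocyte cystine; bedside Schwartz eGFR).

## Worked example

Simulate one patient-like acquisition (standard 78 slices × 2.8 µm;
160 µm field crop) and quantify it:

```r
library(nccv)

g   <- acquisition_geometry(pixel_size_um = 1, field_um = 160)
sim <- simulate_stack(sim_config(geometry = g, n_crystals = 40, seed = 11))
r   <- compute_nccv(sim$stack)
summary(r)
#> Normalized confocal crystal volume
#>   band:               slices 15-50 (42-140 um)
#>   crystal components: 32
#>   crystal volume:     795.2 um^3
#>   structure volume:   347524.8 um^3
#>   analyzed volume:    2.233e+06 um^3
#>   peak profile slice: 27
#>   nCCV:               919.0 um^3

sim$truth$true_crystal_volume_um3
#> [1] 795.2
```

Reading the output: 32 isolated crystal components were reconstructed
in the papillary-dermis band; their summed volume (795.2 µm³) matches
the planted isolated ground truth exactly — the 8 planted in-papilla
confounders were all excluded.  Papillae occupy ~13% of the band here,
so the normalization scales the volume up to 919.0 µm³, the value
comparable across stacks with different structure content.  The profile
peaks at slice 27 (76 µm), inside the band; `plot(r)` draws the
area-versus-depth profile with the band shaded.

Stacks on disk are multi-page grayscale TIFFs with a JSON sidecar
(`pixel_size_um`, `step_um`, subject metadata); see `read_stack()` /
`write_stack()`.  `inst/cli/nccv` exposes `simulate`, `quantify` and
`stats` subcommands over the same functions:

```sh
Rscript inst/cli/nccv simulate --out cohort/ --n-patients 2 --n-controls 2 --seed 7
Rscript inst/cli/nccv quantify cohort/S00*.tif --out results/
Rscript inst/cli/nccv stats results/../cohort/cohort.csv --out results/
```

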