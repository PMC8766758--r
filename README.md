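# strokefield

Quantitative tools for characterizing **homonymous visual field loss after
stroke** by linking clinical perimetry to three brain-imaging measures:
functional population receptive field (pRF) maps, anatomical lesion-atlas
overlap, and diffusion-tensor white-matter microstructure. The package is
aimed at vision scientists and clinical researchers who want to ask, for a
given blind region of the visual field, whether the cortex representing it
is destroyed, disconnected, or still responsive.

## What it computes

**pRF mapping.** Each voxel's receptive field is a circular 2D Gaussian in
visual space (center *x₀, y₀*; size σ). The predicted BOLD response to a
retinotopy stimulus (rotating wedge / expanding ring / sweeping bar
apertures, 24 s period, one frame per 1.5 s TR) is the aperture–Gaussian
overlap convolved with a double-gamma hemodynamic kernel. Parameters are
fitted per voxel by coarse-to-fine nonlinear least squares after 0.01 Hz
high-pass filtering; fit quality is the coefficient of determination
r² = 1 − SS_res/SS_tot, and a voxel counts as *reliable* when its r²
exceeds mean + 3 SD of r² in a non-visual control region.

**Scotoma geometry and residual function.** The perimetric scotoma is the
convex hull of unseen test points. Each reliable pRF, approximated as a
disc of radius σ̂, is tested for intersection with the hull; counts are
expressed in 1 mm standard-space units (each native 3 mm voxel replicated
into 27 unit voxels). The healthy hemisphere provides a within-participant
control by mirroring the hull across the vertical meridian (x ↦ −x).
r² distributions of overlapping voxels in the two hemispheres are compared
with a two-sample Kolmogorov–Smirnov test; visual-field coverage maps
summarize where a region's pRFs respond.

**Perimetry utilities.** The adaptive 6 dB point-expansion rule, mean
deviation against an age-normal hill of vision, and fixation stability as
the bivariate contour ellipse area, BCEA = 2kπ σ_H σ_V √(1−ρ²) with
k = −ln(1−p) at containment fraction p (63% default).

**Lesion quantification.** Percentage of each of the 25 visual-area atlas
ROIs covered by a binary lesion mask (0% = spared, 100% = lost), grouped
into five cortical territories (early visual, ventral, lateral occipital,
dorsal, frontal).

**Diffusion.** Log-linear single-tensor fits, FA/MD, tract volume above a
0.001 probability threshold, and hemispheric percentage change in mean FA.

A synthetic-data module (`make_sheet()`, `simulate_scenario()`,
`make_perimetry_responder()`, `make_dwi_phantom()`,
`make_toy_atlas_and_lesion()`, ...) generates every input with known ground
truth, so the full pipeline runs and is tested without any participant
data.

## Worked example

Simulate a complete left-hemifield loss, fit pRFs, and quantify residual
function inside the scotoma:

```r
library(strokefield)

cfg  <- simulation_config(n_voxels = 100, n_control = 50)
sc   <- simulate_scenario("hemianopia", cfg, seed = 505)
fits <- fit_prf(sc$sheet$series, sc$sheet$apertures,
                search = prf_search_grid(cfg$field_radius))

ctrl <- sc$sheet$truth$hemisphere == "control"
thr  <- reliability_threshold(fits$r2[ctrl])

vis            <- fits[!ctrl, ]
vis$roi        <- "early_visual"
vis$hemisphere <- sc$sheet$truth$hemisphere[!ctrl]
residual_summary(vis, sc$hull, thr)
#>            roi count_mm3 control_count_mm3 D            p n1 n2 status
#> 1 early_visual         0              2511 1 9.122745e-27 45 93     ok
```

Reading the output: in the lesioned hemisphere, **0 mm³** of reliable pRF
tissue responds inside the perimetrically blind region, against
**2511 mm³** for the mirrored control region in the healthy hemisphere,
and the r² distributions of the two hemispheres' overlapping voxels are
maximally separated (D = 1, p ≈ 9 × 10⁻²⁷) — the signature of a complete
hemianopia with no residual function. A participant with cortical sparing
would instead show a non-zero count approaching the control value and a
smaller D.

The same pipeline pieces work standalone, e.g.:

```r
bcea(make_fixation_cloud(1.2, 0.7, 0.4, n = 1e5, seed = 705))$bcea
#> [1] 4.825434   # deg^2 at 63% containment

toy <- make_toy_atlas_and_lesion(c(V1d = 0.3, V2v = 0.5))
subset(roi_loss(toy$lesion, toy$atlas), loss_pct > 0)
#>   roi hemisphere    territory roi_voxels lesion_voxels_in_roi loss_pct
#> 2 V1d       left early_visual        200                   60       30
#> 3 V2v       left early_visual        200                  100       50
```

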