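---
title: "Linking perimetry to imaging markers of visual field loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking perimetry to imaging markers of visual field loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokefield)
```

## The problem

After a post-chiasmal stroke, patients typically lose conscious vision in
part of the contralateral visual field (homonymous hemianopia or
quadrantanopia). Clinical static perimetry maps this loss behaviorally, but
cannot say *why* a location is blind: the cortex representing it may be
destroyed, disconnected, or partially functional ("blindsight"-like residual
responses). `strokefield` implements the quantitative core of a multi-modal
assessment that triangulates among three measurements:

1. **Function** — population receptive field (pRF) mapping from stimulus-
   driven fMRI time series, giving each voxel an estimated visual-field
   position and size, compared against the perimetric scotoma;
2. **Anatomy** — percentage overlap between a lesion mask and the 25
   visual-area ROIs of a maximum-probability atlas, grouped into cortical
   territories;
3. **Microstructure** — diffusion-tensor FA/MD and tract-level hemispheric
   asymmetry.

Because participant scans are not shipped, every input can be generated
synthetically with known ground truth; the test suite exercises the full
pipeline on those fixtures.

## Stimulus model

Retinotopy apertures are binary movies on a square visual-field grid:
a rotating wedge, an expanding (or contracting) ring, and a sweeping bar,
each traversing the field exactly once per 24 s period at one frame per
TR (1.5 s), five cycles per run. The geometry defaults (wedge width 45°,
ring thickness 1/8 of the field radius, bar width 1/4 of the radius,
maximum mapped eccentricity 10°) are standard retinotopy choices, exposed
as parameters rather than asserted as acquisition facts, since stimulus
extent and aperture geometry vary between laboratories. The grid default of
101 × 101 points keeps the quadrature error of Gaussian-aperture overlaps
far below fit tolerances while staying cheap to evaluate. Screen geometry
(viewing distance 119 cm, 1440 × 1080 pixels, 100 Hz) converts between
pixel offsets and degrees of visual angle through the exact arctangent.

## The pRF model and its fit

Each voxel's aggregate receptive field is a circular 2D Gaussian in visual
space, $g(x, y) = \exp\!\left(-\frac{(x-x_0)^2 + (y-y_0)^2}{2\sigma^2}\right)$,
normalized to unit mass on the grid. The predicted response at frame $t$ is
the overlap between the aperture and $g$, convolved with a canonical
double-gamma hemodynamic kernel (positive lobe peaking at 5 s, undershoot
at 15 s, peak:undershoot ratio 6, 30 s support, peak-normalized). The
literature describes the hemodynamic stage only as temporal delay and
blurring; the double-gamma is the least-surprising concrete choice and all
four shape parameters are configurable.

Both data and predictions are high-pass filtered at 0.01 Hz (Fourier-domain
removal of all components below the cutoff, including the mean) so that
slow scanner drift cannot masquerade as stimulus-driven signal.

Fitting is coarse-to-fine nonlinear least squares:

* **Grid stage.** Candidate centers on a 17 × 17 lattice spanning the
  mapped field crossed with $\sigma \in \{0.5, 1, 2, 4\}°$; the amplitude
  is solved in closed form at each node (the predictor is projected at unit
  norm, which is also overflow-safe when a candidate pRF barely overlaps
  the stimulus). Ties break to the first node in row-major order.
* **Refinement.** Bounded quasi-Newton (L-BFGS-B) over $(x_0, y_0, \sigma)$
  with centers allowed out to 1.5 × the field radius (edge pRFs) and
  $\sigma \in [0.1°, \text{field radius}]$. The residual surface of
  travelling-wave designs can be multimodal, so refinement restarts from
  the three best grid nodes with distinct centers and keeps the best
  optimum. The refinement result is only accepted when it improves on the
  grid-stage residual, so the fit can never be worse than the coarse
  search.

Goodness of fit is $r^2 = 1 - SS_{res}/SS_{tot}$ — the coefficient of
determination, not a squared correlation — which is invariant to affine
rescaling of the measured series. Constant (zero-variance) series return
$r^2 = 0$ with a `degenerate` flag rather than an error. Amplitudes may be
negative; reliability is judged on $r^2$ alone, as a threshold of
mean + 3 SD of the $r^2$ distribution in a non-visual control region.
The whole fit is deterministic given the series, search grid and optimizer
settings.

Repeated scans are expected to be averaged time-locked before fitting (the
generator produces one series per voxel per run); concatenation works too,
by passing one aperture per run.

## Perimetry, scotoma geometry, fixation stability

* **Adaptive expansion.** When a tested location falls more than 6 dB
  (strict) below the age-normal hill of vision, its four grid neighbors are
  queued, excluding already-tested points and points beyond the device
  extent (50° default). The rule is idempotent once the recruited points
  test normal.
* **Mean deviation** is the mean of measured − normal over tested points
  (negative = loss). Published clinical tables are inconsistent in sign
  across devices, so the convention is explicit and configurable; unseen
  points enter at a configurable floor (0 dB default).
* **Scotoma hull.** The scotoma is summarized as the convex hull of unseen
  points. Degenerate cases are first-class: one unseen point yields a
  point-hull, collinear points a segment-hull, an intact field an explicit
  empty sentinel — downstream intersection tests handle all three, so the
  pipeline never throws on a clean field.
* **BCEA.** Fixation stability is the bivariate contour ellipse area
  $2 k \pi \sigma_H \sigma_V \sqrt{1-\rho^2}$ with
  $k = -\ln(1 - p)$ at containment fraction $p$ (0.63 default). Sample
  (n−1) standard deviations and the Pearson correlation are used, and $k$
  comes from the exact logarithmic relation rather than a fixed constant,
  so any requested containment fraction is honored; a Monte-Carlo test
  confirms the ellipse contains 63.2% ± 2% of a 100,000-sample cloud.

## Residual function inside the scotoma

Each reliable pRF is approximated as a closed disc of radius $\hat\sigma$
at $(\hat x_0, \hat y_0)$. A disc intersects the (closed) scotoma hull iff
its center is inside or within $\hat\sigma$ of the boundary; tangency
counts as intersection, and agreement with a 0.02° rasterization oracle is
part of the acceptance suite. Counts are reported in 1 mm standard-space
units by replicating each native 3 mm voxel into 27 unit voxels with no
interpolation — the native fit stays authoritative, the count gains mm³
units, and the native identity is recoverable from every replicate.

The control for the lesioned-hemisphere count is the same count in the
healthy hemisphere against the hull mirrored across the vertical meridian
($x \mapsto -x$), which cancels hemisphere-level differences in ROI size
and fit quality. Hemisphere assignment comes from the anatomical label of
the voxel, never from the sign of $\hat x_0$, because ipsilateral-field
pRFs exist near the meridian.

Distributions of fit quality are compared with a two-sample
Kolmogorov–Smirnov test: $D$ is the exact supremum over the pooled sample
sweep and $p$ comes from the asymptotic Kolmogorov distribution at
effective size $n_1 n_2/(n_1+n_2)$ (small-sample exactness is unnecessary
where reported bounds are as extreme as $10^{-8}$). One $r^2$ per uniquely
identified native voxel enters the test; when either side has no
overlapping voxels the result is a `no_overlap` sentinel, not an error.
The KS comparison uses all unique voxels whose fitted disc overlaps the
(mirrored) region, without the reliability filter — filtering first would
empty the stroke-side sample exactly in the severe cases the test is meant
to characterize — while the counts themselves use the threshold.

Coverage maps summarize where a region's voxels respond: the value at each
field point is the **maximum** over fits of the voxel's Gaussian profile
(peak-normalized, or amplitude-scaled in non-normalized mode). Max rather
than sum matches the coverage-map literature and makes maps monotone
non-decreasing and permutation-invariant in the fit list; the combination
rule is exposed as a flag.

## Lesion quantification

Lesion damage is the percentage of each atlas ROI's voxels inside the
binary lesion mask (0% = spared, 100% = lost), computed by exact integer
voxel counting on a common grid — the denominator is always the ROI volume
on the grid supplied. ROIs group into five cortical territories (early
visual, ventral, lateral occipital, dorsal, frontal); the published
grouping enumerates 24 ROI names while the atlas has 25, so IPS0 is
assigned to the dorsal territory here. Territory summaries are
ROI-voxel-weighted means by default (an unweighted mean is available),
since ROIs differ in size by an order of magnitude. The real probabilistic
atlas is not shipped; a toy atlas of 25 disjoint 200-voxel boxes per
hemisphere with engineered lesion fractions stands in for it, and any
maximum-probability label volume on the same grid as the mask can be
substituted.

## Diffusion microstructure

Single-tensor fits use unweighted log-linear least squares on
$\ln S = \ln S_0 - b\, g^\top D g$ (the canonical baseline; a
signal-weighted variant is available), followed by eigendecomposition with
negative eigenvalues clamped to zero and flagged. FA and MD follow the
standard closed forms; FA of an all-zero tensor is defined as 0. Tract
statistics threshold probability maps strictly above 0.001 (the floor value
itself is excluded) and report suprathreshold volume and unweighted mean
FA; hemispheric asymmetry is $100(\text{lesioned}-\text{healthy})/\text{healthy}$.
The synthetic acquisition matches the target protocol: b = 1000 s/mm², 60
Fibonacci-spread directions plus one b = 0 volume.

## The synthetic cortex and what it does (not) show

The generator draws pRF centers quasi-uniformly over each hemisphere's
contralateral hemifield plus a 1° ipsilateral strip, with
$\sigma = 0.1 + 0.25\,e$ degrees at eccentricity $e$ — a plausible
early-visual size-eccentricity scaling; no per-area model is asserted.
Noise is white Gaussian at SD = 0.2 × response amplitude by default, with
an optional AR(1) component (ρ = 0.3) to stress the high-pass filter. A
voxel is silenced (series replaced by pure noise) when its true pRF disc
lies entirely inside the scotoma polygon; the rule applies only to the
configured lesioned hemisphere, because the healthy hemisphere's afferents
are intact. Scenario presets extend the silencing polygon well beyond the
mapped field as a cortical-lesion proxy, so complete hemianopia silences
the lesioned hemisphere's entire map while the perimetry-facing scotoma
remains the blind hemifield itself. The synthetic perimetry responder
marks the strict interior of the scotoma polygon unseen — points on the
vertical meridian count as seen, as in clinical charts. The normative hill
of vision fixture is 30 dB at fixation falling 0.3 dB/degree.

What passing tests show: the estimator recovers known ground truth at
realistic noise, the mirror-flip control is unbiased under the null, and a
synthetic hemianopia reproduces the qualitative signature (collapsed
lesioned-hemisphere counts, extreme KS separation). What they do not show:
robustness to draining-vein geometry, spatial noise correlations, head
motion, EPI distortion, or fixation instability — real-data effects the
generator deliberately omits.

## Numerical choices and problem sizes

* Grid-stage predictions for all nodes are built as one matrix product;
  refinement uses a per-fit context in which the HRF convolution and the
  high-pass filter (both linear in time) are pre-applied to the aperture
  design matrix, and each candidate Gaussian is evaluated only on its
  numerically relevant support.
* Optimizer: L-BFGS-B, `factr = 1e7`; convolution is causal and truncated
  to the series length; $\sigma$ below half a grid step triggers a warning
  but is still evaluated.
* Tangent disc/hull configurations resolve as intersecting (closed sets).
* The property suite runs at deliberately chosen sizes: 200 voxels for
  recovery, 100 + 100 for threshold separation, 100 replicates of a
  60-voxel-per-hemisphere symmetric brain for the flip-control null (using
  grid-stage estimates, whose symmetry the control inherits; the nonlinear
  stage is exercised at full depth everywhere else), 1000 random
  disc/hull cases against the rasterization oracle, and 100,000-sample
  BCEA clouds.
* All generators are pure functions of (config, seed) and restore the
  caller's RNG state; every pipeline stage is bit-reproducible under a
  fixed seed.

## Known limitations

Single-Gaussian pRFs only (no difference-of-Gaussians or compressive
variants); no motion correction, slice timing or registration (upstream
tools' jobs); tract probability maps are inputs, not computed (ball-and-
stick modeling and probabilistic tractography live in external toolboxes);
the microperimetry "pattern defect" score has no published formula and is
deliberately not implemented; published per-participant perimetry indices
are not reproducible without the original data and are not targeted.
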