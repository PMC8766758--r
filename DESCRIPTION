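Package: strokefield
Title: Multi-Modal Characterization of Homonymous Visual Field Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking clinical perimetry to brain-imaging measures of
    visual field loss after stroke. Implements population receptive field (pRF)
    mapping from stimulus-driven time series (wedge, ring and bar apertures,
    canonical hemodynamic convolution, coarse-to-fine nonlinear least squares),
    perimetry utilities (adaptive test-point expansion, mean deviation, scotoma
    convex hulls, bivariate contour ellipse area for fixation stability),
    residual-function statistics inside the scotoma (supersampled pRF
    intersection counts with a mirror-flip hemisphere control, visual field
    coverage maps, Kolmogorov-Smirnov comparison of fit quality), atlas-based
    lesion quantification over 25 visual-area ROIs grouped into cortical
    territories, and single-tensor diffusion metrics (FA, MD, tract volume and
    hemispheric asymmetry). A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable without participant
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
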