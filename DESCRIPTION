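Package: trabkit
Title: Trabecular Bone Microarchitecture Quantification from 2D Images
Version: 0.1.0
Authors@R: person("Trabkit", "Developers", email = "trabkit@example.org",
    role = c("aut", "cre"))
Description: Quantifies trabecular bone microarchitecture on 2D grayscale
    slices from micro-computed tomography or high-field magnetic resonance
    imaging. Provides local-threshold and three-phase segmentation,
    aperture-map (local thickness) histomorphometry (bone volume fraction,
    trabecular thickness, spacing and number), multi-scale Hessian
    orientation analysis with a dual-Gaussian orientation-mixture fit
    yielding principal/secondary trabecular orientation and a trabecular
    interconnectivity metric, air-bubble volumetry, integer block-merge
    resolution degradation, slice-to-stack affine registration with
    mutual-information scoring, method-agreement statistics (Kruskal-Wallis,
    ordinary least squares, Bland-Altman, intraclass correlation), and a
    synthetic trabecular phantom generator with exact ground truth. Reads
    and writes uncompressed TIFF, NIfTI-1 and MetaImage rasters with
    physical pixel spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
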