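Package: hemidti
Title: Interhemispheric Diffusion Tensor Imaging Analysis of Radiation-Induced White-Matter Damage
Version: 0.1.0
Authors@R:
    person("hemidti", "developers", email = "hemidti@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of diffusion tensor imaging (DTI) data for
    quantifying radiation-therapy-induced white-matter damage in brain-tumor
    patients via global interhemispheric fractional-anisotropy differences
    (delta-FA). Provides a Rician-noise DWI phantom generator with known
    ground truth, log-linear diffusion tensor fitting with FA/MD/AD/RD maps,
    rigid halfway registration and per-subject b0 template construction,
    tumor-centered ROI and whole-hemisphere asymmetry statistics, exact and
    approximate nonparametric cohort statistics, and voxelwise whole
    brain-based spatial statistics (WBSS) with FDR correction and
    cluster-size filtering. Includes minimal NIfTI-1 and FSL-dialect
    bvec/bval input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
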