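Package: anisosim
Title: Anisotropic Similarity Registration and Directional Growth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear registration of 3D medical images using the anisotropic
    similarity transformation, a 9 degree-of-freedom affine transformation
    whose scaling directions are fixed a priori. Provides a quaternion-based
    alternating least-squares estimator of the optimal anisotropic similarity
    between paired 3D point sets, a block-matching registration engine built
    on it, construction of the constrained scaling frame from the mid-sagittal
    plane and in-plane principal components, and the downstream cohort
    analysis: extraction and normalization of directional scaling factors,
    growth-curve fitting with AICc-based model selection and Akaike weights,
    FDR-controlled group comparisons, and reference-image influence metrics.
    Deterministic synthetic phantoms, point sets and cohorts are included so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'anisosim-package.R'
    'transform.R'
    'image.R'
    'pointset.R'
    'quaternion.R'
    'fit.R'
    'blockmatch.R'
    'frame.R'
    'growth.R'
    'scaling.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
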