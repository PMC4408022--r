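Package: bctshape
Title: Multifactorial Simulation of Breast Contour After Breast-Conserving Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional modelling pipeline for the cosmetic outcome of
    breast-conserving therapy (lumpectomy plus whole-breast radiotherapy).
    The package couples quasi-incompressible Neo-Hookean plane-strain finite
    element mechanics of the breast under gravity with a hexagonal-lattice
    cellular automaton of wound healing driven by a growth-factor
    reaction-diffusion equation, and calibrates the coupled model against
    observed breast contours with a raster objective minimised by grid
    search over four clinical phases of healing (baseline, inflammation,
    proliferation, radiotherapy).  A synthetic breast-phantom generator,
    fuzzy C-means tissue segmentation, Tikhonov skin smoothing and simple
    cosmesis metrics make the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
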