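Package: stodeo
Title: Structural Modeling Magnitude and Orientation Radiomics for
    Hollow-Organ Walls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the magnitude and direction of structural
    displacement of a hollow-organ wall (e.g., the rectal wall on T2w MRI)
    relative to a non-diseased reference atlas. Provides a lightweight
    deformable registration engine (rigid, affine and cubic b-spline
    free-form deformation driven by normalized mutual information),
    transform inversion, and extraction of per-voxel displacement fields;
    computes the StODeO descriptor (first-order statistics of displacement
    magnitude plus a five-bin inward/outward orientation histogram isolated
    by Markov-random-field clustering), traditional texture radiomics
    (Gabor, Sobel gradient, CoLlAGe), minimum-redundancy maximum-relevance
    feature selection with LDA/QDA/random-forest cross-validated
    classification, consensus clustering and Spearman/positive-FDR
    correlation mapping, and a hollow-tube phantom generator with analytic
    ground-truth deformation fields for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    Rtsne,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
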