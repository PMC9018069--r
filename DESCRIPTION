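Package: neuroexcursion
Title: Manifold Excursion and Covariance-Geometry Analysis of Sensorimotor
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing human sensorimotor adaptation with
    functional-neuroimaging network measures. Implements learner phenotyping
    from visuomotor-rotation error curves (circular early error, savings,
    complete-linkage clustering with parametric-bootstrap validation),
    estimation of a subject's resting-state neural manifold by PCA and the
    per-volume off-manifold excursion statistic, smoothing and multivariate
    functional PCA of excursion trajectories with rank-based group tests,
    affine-invariant Riemannian operations on covariance matrices (log and
    exp maps, parallel transport, Frechet mean, subject centering), and a
    joint rank-one embedding of covariance tangent vectors. A synthetic-data
    generator reproduces the statistical structure the analysis assumes, so
    every stage has a ground-truth recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
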