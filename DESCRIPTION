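Package: tolnorm
Title: Reaction-Norm Quantitative Genetics of Disease Resistance and Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based REML animal models for the genetic analysis of
    disease tolerance treated as a reaction norm of host performance on
    disease severity. Provides pedigree algebra (inbreeding, numerator
    relationship matrix and its sparse inverse), a restricted maximum
    likelihood engine for trait-mean, bivariate and random-regression
    animal models with heterogeneous residual classes, plateau-linear
    covariate coding with information-criterion threshold selection,
    covariance-function trajectories of variance, heritability and
    genetic correlation along a severity axis, and a seeded simulator of
    sire-dam broiler populations with correlated additive-genetic and
    maternal effects for body weight and ascites indicator traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
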