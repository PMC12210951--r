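Package: fermkin
Title: Fermentation Kinetics, Orthogonal-Design ANOVA and ANN-GA Medium
    Optimization for Lactic Acid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-density lactic acid bacterium
    fermentations. Fits coupled logistic growth and Luedeking-Piret
    product-formation and substrate-consumption models to batch time
    series by bound-constrained nonlinear least squares, with
    linearization-based confidence intervals and goodness-of-fit
    reporting. Provides L9(3^3) orthogonal-array main-effects ANOVA with
    classical eta-squared effect sizes and Tukey post-hoc comparisons,
    Box-Behnken design generation, a Bayesian-regularized feed-forward
    neural-network surrogate trained by Levenberg-Marquardt with
    evidence-framework hyperparameter updates, and a real-coded genetic
    algorithm with elitism and stochastic universal sampling for medium
    optimization over the surrogate. Includes closed-form assay
    arithmetic (titratable acidity, DNS glucose standard curves, resin
    adsorption capacity, log-scale fold changes), seeded synthetic-data
    generators for every stage, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
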