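Package: PatternSeverity
Title: Multidimensional Graded Response Modelling of Two-Factor Symptom
    Pattern Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the severity of a two-factor traditional-medicine
    symptom pattern from short polytomous questionnaires. Implements the
    multidimensional graded response model (category probabilities under
    probit or logistic links, multidimensional discrimination, item and
    test information surfaces, expected a posteriori severity scoring),
    marginal maximum-likelihood estimation by an EM algorithm with tensor
    Gauss-Hermite or quasi-Monte-Carlo integration under confirmatory
    simple-structure constraints with a free latent correlation,
    maximum-likelihood confirmatory factor analysis with CFI, RMSEA and
    AIC fit indices for unidimensional versus two-factor comparison,
    classical reliability statistics, and a synthetic-respondent
    generator driven by a packaged nine-item liver-stagnation
    spleen-deficiency item bank.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
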