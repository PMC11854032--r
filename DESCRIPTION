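Package: nlwdist
Title: The New Lomax-G Family and the New Lomax-Weibull Lifetime Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the new Lomax-G family of lifetime distributions,
    generated by composing a baseline distribution with the exponentiated
    reciprocal hazard rate of the Lomax distribution, and for its
    Lomax-Weibull member (NLW). Provides density, distribution, quantile,
    survival, hazard and random-generation functions, moments, generating
    functions, probability-weighted moments, order statistics, Renyi and
    Shannon entropies, and quantile-based shape measures. Parameters can be
    estimated by maximum likelihood (with analytic score), percentile,
    ordinary and weighted least squares, and Cramer-von Mises minimum
    distance. Includes a Monte Carlo harness for bias and mean-squared-error
    comparison of the estimators, a goodness-of-fit engine (AIC, BIC, CAIC,
    HQIC, Kolmogorov-Smirnov, Anderson-Darling) with competing lifetime
    models, four classical reliability datasets, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
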