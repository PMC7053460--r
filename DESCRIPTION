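Package: frlx
Title: Flexible Reduced Logarithmic-X Family of Lifetime Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the flexible reduced logarithmic-X (FRL-X) family of
    lifetime distributions: the generic one-parameter cdf transform over an
    arbitrary baseline distribution, the FRL-Weibull submodel and its
    extended (exponentiated) variants, competitor lifetime models
    (Weibull, alpha-power-transformed Weibull, Marshall-Olkin Weibull),
    maximum-likelihood fitting with standard errors, goodness-of-fit
    statistics (Anderson-Darling, Cramer-von Mises, Kolmogorov-Smirnov
    with asymptotic p-values) and scaled total-time-on-test coordinates,
    multi-model comparison reports, and a reproducible Monte Carlo
    harness for bias and mean-squared-error studies of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
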