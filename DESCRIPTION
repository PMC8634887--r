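Package: latentWMW
Title: Wilcoxon-Mann-Whitney Tests for Latent Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rank-based two-group comparison of a latent construct measured
    by several error-prone indicators. Indicators are aggregated into a
    composite score, either as the unweighted mean of the pooled-standardized
    indicators or as a maximally reliable weighted composite whose weights are
    derived from triad-based estimates of the measurement-error variances.
    The two-group hypothesis on the latent distribution is tested through the
    probabilistic index with normal, exact or permutation inference. The
    package also provides sample-size and power calculations for the design
    of such studies, and a seeded Monte Carlo engine that evaluates empirical
    type I error and power of the rank test and of Welch t-test competitors
    over a grid of latent distributions, reliabilities, sample sizes and
    measurement-error misspecifications.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
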