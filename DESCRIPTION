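Package: plateletkin
Title: Numerical Analysis of In Vivo Platelet Consumption Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time cohort model of circulating platelet kinetics in
    which platelets are produced hourly and consumed by two concurrent
    processes: an age-independent random destruction rate and a
    lifespan-dependent process governed by a lognormal intrinsic-lifespan
    distribution. Provides equilibration of the cohort matrix, equilibrium
    age distributions, normalized post-production consumption (survival)
    curves, and population turnover diagnostics; a grid-search least-squares
    fitter that recovers the random destruction rate, median lifespan, and
    lifespan dispersion from labeled-platelet survival data; grafting of a
    donor strain's equilibrium age distribution into a recipient environment
    for allogeneic transfusion studies; delete-one jackknife standard errors
    and Welch comparisons of fitted parameters; and a synthetic-data
    generator for study design and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
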