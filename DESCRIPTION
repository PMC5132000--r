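Package: exofrailty
Title: Time-to-Event Analysis of Single-Granule Exocytosis with Discrete
    Frailty and Cluster-Robust Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the timing of single secretory-granule exocytosis under
    pulsed depolarization as clustered right-censored time-to-event data.
    Provides piecewise-constant hazard (piecewise-exponential / Poisson)
    regression over a pulse-train stimulation protocol, a discrete two-point
    frailty mixture describing an immediately releasable pool (IRP) of
    granules, maximum-likelihood estimation of the marginal independence
    likelihood, cluster-robust sandwich variance, Chandler-Bate adjusted
    log-likelihood ratio tests (including boundary-mixture nulls for pool
    probabilities) and profile-likelihood confidence intervals, Kaplan-Meier
    reporting, and a synthetic-data generator with cell-level heterogeneity
    for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    sandwich,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
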