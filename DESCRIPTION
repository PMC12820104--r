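Package: pfsratio
Title: Design and Analysis of Phase II Trials with the PFS Ratio Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-arm precision-oncology phase II trials that use the
    progression-free survival ratio (PFSratio, also known as growth modulation
    index) as their endpoint. Implements five estimators of the probability
    P(PFS2/PFS1 >= delta) under right censoring of PFS2, including a two-stage
    kernel-based Kaplan-Meier estimator that remains valid under the informative
    censoring inherent to ratios of paired failure times; diagnostics for paired
    PFS outcomes (Kaplan-Meier summaries, Weibull adequacy check, Weibull-Gamma
    frailty fit with Kendall's tau); modified-PFSratio transforms; sample-size
    and power calculators based on the generalized treatment effect under
    Gumbel-type-B bivariate exponential and Weibull-Gamma frailty assumptions;
    and bivariate survival simulators with calibrated censoring mechanisms for
    benchmarking estimator bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
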