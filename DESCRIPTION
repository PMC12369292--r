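Package: ccbmd
Title: Benchmark Dose Modeling for Case-Control Dose-Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmark dose (BMD) estimation from published case-control
    study summary tables. Adjusted odds ratios are modeled along two
    parallel tracks: converted to "effective" case/non-case counts and fit
    as dichotomous data (quantal-linear and dichotomous Hill models under a
    Gamma-extended binomial likelihood), or treated directly as lognormal
    continuous responses (linear and Hill models under a summary-statistics
    normal likelihood). Includes water-intake-adjusted exposure midpoint
    computation for open-ended dose intervals, Wang-style referent-group
    effective-count estimation, equivalent benchmark-response calibration
    between the two tracks, Bayesian fitting by adaptive Markov chain Monte
    Carlo with posterior BMD/BMDL/BMDU summaries, cross-track agreement
    statistics, and a synthetic case-control generator for recovery testing.
    Ships the bladder and lung cancer arsenic exposure tables the framework
    was calibrated on.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
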