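Package: betadose
Title: Optimal Experimental Design for Beta-Regression Dose-Response Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based design of concentration-response experiments under the
    dose-parametrized Beta regression model, in which flask-level response
    rates are Beta distributed with log-linear shape parameters in dose.
    Provides the model itself (density, sigmoidal mean response, lethal
    concentrations LCp with delta-method gradients, maximum-likelihood
    fitting of grouped rate data), Fisher information and the D-, c(LCp)-
    and dual-objective design criteria with pseudo-Bayesian averaging over
    several nominal parameter sets, a grid-based exchange algorithm with
    equivalence-theorem convergence certificates, efficiency auditing of
    arbitrary designs (uniform, ad-hoc), and a seeded synthetic-data
    generator for validating fits and delta-method variances. Results are
    tibbles throughout, with broom-style tidy()/glance() methods and
    ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
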