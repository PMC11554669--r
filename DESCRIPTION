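Package: vaxcop
Title: Immune Correlates and Immunogenicity-Based Vaccine Efficacy for
    Time-to-Event Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Immune-correlates analysis of vaccine trials with right-censored
    time-to-event endpoints. Assesses an immunogenicity biomarker as a
    correlate of risk (AIC-guided Cox, cause-specific and Fine-Gray model
    selection) and as a correlate of protection (Prentice conditional
    independence test), and estimates subgroup vaccine efficacy by averaging
    fitted hazard-ratio risk curves over the observed immunogenicity
    distributions of the vaccinated and control arms. Confidence intervals
    combine a stratified subject-level bootstrap with multivariate-normal
    resampling of model coefficients. Includes case-count (incidence-rate)
    vaccine efficacy with an exact conditional-binomial interval, a
    synthetic-trial simulator with an analytic true-efficacy oracle, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cmprsk,
    dplyr,
    generics,
    ggplot2,
    MASS,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
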