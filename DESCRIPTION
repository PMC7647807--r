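Package: padstress
Title: Acute Stress Detection from Laptop Trackpad Finger Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to detect acute stress from multi-touch trackpad finger
    dynamics. Implements stroke segmentation of jittered multi-finger event
    logs, mass-spring-damper parameter extraction (damping ratio and damped
    frequency) from the largest continuous stroke via AR(2) linear-predictive
    fitting, contact-area and kinematic trial metrics, electrodermal activity
    (EDA) filtering, tonic/phasic decomposition and skin-conductance-response
    counting, and a routed paired-statistics protocol (Shapiro-Wilk gated
    paired t / Wilcoxon tests, Cohen's d, noncentral-t post hoc power,
    Order-by-Condition ANOVA, Bonferroni-corrected task-specific models and
    sensitivity subsets). A synthetic-study generator with known ground truth
    emulates the trackpad logger, self-reports and wrist EDA so that every
    stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
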