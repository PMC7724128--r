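Package: doublelist
Title: Double List Experiment Analysis for Sensitive Health Behaviours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and diagnostics for (double) list experiments, an
    indirect questioning design used to measure the prevalence of sensitive
    health behaviours such as condom use or intimate partner violence.
    Provides difference-in-means prevalence estimators with robust and
    respondent-clustered standard errors, Wald tests of misreporting against
    direct self-reports and of internal consistency between lists,
    randomisation-balance, design-effect and ceiling/floor diagnostics,
    double-list efficiency accounting, and the bias-variance minimum sample
    size calculation, together with a synthetic respondent simulator for
    validating the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
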