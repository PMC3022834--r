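Package: cd4slope
Title: CD4 Count Slope Versus Concurrent HIV Viral Load on Combination
    Antiretroviral Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying trends in CD4 lymphocyte counts (slopes,
    cells/uL per year) in relation to the concurrent HIV viral load after
    initiation of combination antiretroviral therapy (cART). Provides a
    seeded synthetic-cohort generator for long-format patient, laboratory,
    clinical-event and treatment tables; construction of three-point CD4
    slope endpoints from concurrent CD4/viral-load test pairs with
    time-updated covariates; a from-scratch random-intercept linear mixed
    model estimated by profile REML with univariate scans and forward
    selection; a slope calculator that predicts CD4 slope from patient
    covariates and solves for the viral-load level compatible with a target
    slope; and a pipeline driver that runs the whole analysis reproducibly
    from a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
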