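Package: effindex
Title: Early Fertility Fragility Index Construction and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite regional fragility indices from administrative
    count registries. Reads department-year tables of births by maternal age,
    health-insurance affiliations, domestic-violence reports and deaths by
    cause; harmonizes them onto a rectangular panel with linear-interpolation
    imputation; computes ten epidemiological indicators (affiliation shares,
    early fertility rates, violence shares, violent-death rates); standardizes
    them by Z-score; aggregates them into the Early Fertility Fragility Index
    (EFFI) with backward-elimination refinement of the predictor set through a
    Gaussian generalized linear model; and validates the index against
    relative changes in early fertility rates with Spearman rank correlation.
    Includes a synthetic registry generator with a planted latent fragility
    factor for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
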