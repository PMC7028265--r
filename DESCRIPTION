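Package: hepetio
Title: Hierarchical Etiology Assignment for Chronic Liver Disease in
    Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a chronic-liver-disease and cirrhosis etiology (hepatitis
    C, hepatitis B, alcohol-related, NAFLD/cryptogenic, autoimmune, or
    hereditary hemochromatosis) to patients in linked administrative
    healthcare data using a hierarchical algorithm that combines viral
    hepatitis serology with ICD-9/ICD-10 diagnosis-code lists. Includes the
    diagnostic-accuracy machinery used to validate such phenotyping
    algorithms against gold-standard chart review (sensitivity, specificity,
    predictive values and Cohen's kappa with confidence intervals, stratified
    by cirrhosis status, with privacy small-cell suppression) and a synthetic
    linked-cohort simulator with a known observation model for end-to-end
    testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
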