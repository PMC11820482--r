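Package: wbq
Title: Water Balance Questionnaire Scoring and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores the Water Balance Questionnaire (WBQ), a semi-quantitative
    instrument for estimating daily water intake (foods, beverages, plain
    water), water loss (urine, feces, sweat) and net water balance in mL/day,
    and reproduces a complete cross-sectional analysis pipeline around it:
    descriptive gender comparisons, univariate linear screens of water-balance
    determinants, multiple imputation by chained equations with Rubin's-rules
    pooling, backward-AIC model selection, regression diagnostics, and a
    synthetic-cohort generator with plantable linear effect structure and
    configurable MCAR/MAR missingness for end-to-end validation without
    access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car,
    lmtest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
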