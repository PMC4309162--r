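Package: sulfateScreen
Title: Call-Aware Fold-Change Screening and Resupply Response Classification
    for Nutrient Starvation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sulfate starvation/resupply expression
    time courses measured on detection-call-aware platforms (e.g. ATH1
    arrays processed with MAS 5.0). Implements fold-change responder
    screening filtered by present/marginal detection calls with
    intersection across experimental replicates, rule-based response
    classification from the sign pattern of resupply contrasts,
    cross-nutrient (nitrogen/phosphorus) specificity categorisation,
    transcription-factor to target-set co-behaviour scoring on log2
    fold-change profiles, Welch t-test metabolite statistics, and a
    synthetic-data generator with planted ground truth for end-to-end
    recovery testing.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
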