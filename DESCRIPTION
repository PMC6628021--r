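Package: apqi
Title: Disease-Specific Antibiotic Prescribing Quality Indicators for
    Out-of-Hours Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes disease-specific antibiotic prescribing quality
    indicators (APQI) from encounter-level out-of-hours primary care
    records: for each indication the percentage of eligible patients
    prescribed an antibiotic, the percentage of treated patients receiving
    the guideline-recommended antibiotic, and the percentage receiving
    quinolones, classified against acceptable ranges and summarized with
    between-site variation. Also describes antibiotic prescribing by
    indication and ICPC-2 chapter, applies a DU90%-style appraisal of how
    many indications cover 90% of antibiotic prescriptions, assembles
    benchmark feedback reports, and provides a seed-reproducible synthetic
    encounter generator calibrated to published Belgian out-of-hours
    values for testing the full pipeline without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
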