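Package: extufail
Title: Rule-Based Detection of Extubation Failure in ICU Flow-Sheet Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements an automated electronic search algorithm that
    identifies extubation failure (endotracheal reintubation within 72
    hours of a prior extubation) from nurse-charted ICU flow-sheet rows
    ("Airway Tube Status", "Airway Tube Type"), together with the
    derivation/validation accuracy machinery used to evaluate such
    computable phenotypes: patient-level confusion tables, sensitivity,
    specificity, predictive values with continuity-corrected Wilson score
    or Clopper-Pearson confidence intervals, and a synthetic flow-sheet
    generator that plants true failures and the documented false-positive
    and false-negative charting modes (nasal trumpets, accidental and
    procedural reintubations, miscoded status values, out-of-ICU
    intubations) with known gold labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
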