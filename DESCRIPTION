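Package: niptr
Title: Shallow-Sequencing Non-Invasive Prenatal Testing for Fetal Trisomy 18 and 21
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for z-score based detection of fetal trisomy 18
    and 21 from shallow whole-genome sequencing of maternal plasma cell-free
    DNA. Provides a synthetic cfDNA cohort generator with a trisomy dosage
    model, read-level quality control (3' quality trimming, length and GC
    filters, positional duplicate removal, unique-mapping selection), fixed
    300 kb genomic binning, per-chromosome representation statistics scored
    against a euploid reference panel, dot-diagram (Youden) cutoff selection,
    and predictive-value evaluation with exact (Clopper-Pearson) and Wilson
    binomial confidence intervals plus an all-success sample-size planner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
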