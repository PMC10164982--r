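Package: mirnorm
Title: Endogenous Control Selection and Relative Quantification for miRNA qPCR Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for selecting stable endogenous-control miRNAs and
    quantifying relative miRNA expression from qPCR and small-RNA sequencing
    data. Implements four reference-gene stability statistics (geNorm M value,
    NormFinder model-based stability, BestKeeper descriptive statistics, and
    the comparative delta-Ct method), RefFinder-style aggregation of their
    rankings by geometric mean, coefficient-of-variation exclusion of
    candidate normalizers, RPM-based candidate screening from sequencing
    counts with differential-expression consensus filtering, relative
    quantification by the 2^-ddCt method with inter-run calibration, and a
    multi-miRNA logistic diagnostic panel with ROC evaluation. Includes
    synthetic-data generators with planted ground truth so the full workflow
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
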