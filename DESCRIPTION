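Package: epitf
Title: Bin-Resolved Modeling of Transcription-Factor Binding from Epigenetic Marks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the relationship between epigenetic modification
    levels and transcription-factor (TF) binding affinity at 100-bp
    resolution around transcription start sites and enhancer midpoints.
    Provides anchor-centered 80-bin window construction, per-bin signal
    quantification from aligned-read tracks (RPM-normalised coverage) and
    CpG methylation tables, per-bin random-forest and multiple-linear
    regression of TF binding affinity on twelve epigenetic features with
    repeated-split cross-validation, out-of-bag permutation-importance
    ranking, cross-context (cell line, gene class, enhancer) model
    transfer, and a synthetic-data generator with a known bin-dependent,
    cell-line-specific link between features and binding so the whole
    pipeline can be exercised end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    IRanges,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
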