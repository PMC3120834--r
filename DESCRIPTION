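Package: solmir
Title: IsomiR Spectra and 3' Non-Template Additions from SOLiD Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls isomiRs and 3' non-template nucleotide additions
    (adenylation, uridylation) against miRNA precursor references from
    SOLiD two-base colorspace or base-space small RNA reads, builds
    per-locus isomiR spectra, profiles miRNA expression under the
    most-abundant-isomiR and sum-of-isomiRs schemes, calls differentially
    expressed miRNAs and modified isomiRs by imputed fold change, and
    infers dominant Drosha/Dicer cleavage sites from end-position
    heterogeneity. Includes a synthetic read generator with planted
    ground truth for three-sample (normal / mild / severe pre-eclampsia
    style) study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
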