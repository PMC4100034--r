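Package: codonsel
Title: Codon Usage Bias and Translational Selection Across Expression Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates per-gene codon usage bias with the Codon Deviation
    Coefficient (a composition-aware bias statistic with bootstrap
    significance), classifies genes by expression pattern
    (expression-invariable, expression-variable, tissue-specific) from a
    multi-tissue RPKM matrix, identifies optimal codons from tRNA gene copy
    numbers, and provides the relative synonymous codon usage (RSCU) and
    correlation analyses used to compare the strength of translational
    selection between housekeeping and tissue-specific genes. Ships a
    synthetic-data generator so the full pipeline is exercisable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
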