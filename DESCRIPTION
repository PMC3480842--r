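Package: triformr
Title: Model-Free Peak Detection for Transcription-Factor ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor binding sites in ChIP-Seq data with
    the Triform approach: nonparametric Hoel tests for three peak-like coverage
    forms at a fixed flank spacing, a control-based enrichment test and
    enrichment-ratio filter, cross-strand pairing with an inter-strand lag
    test, and merging of partial peak forms. Includes BED readers and writers,
    strand-specific coverage tracks built on run-length encodings, a synthetic
    ChIP-Seq read simulator with planted binding sites for end-to-end
    validation, and tidy accessors with ggplot2 diagnostics.
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
    IRanges,
    jsonlite,
    optparse,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
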