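Package: lincscd
Title: Stop-Codon Density and Splice-Enhancer Motif Analysis for Noncoding RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Coverage-based codon and motif density metrics for transcript
    sequences, with compositionally matched codon-set controls,
    dinucleotide-matched motif nulls, mononucleotide shuffle nulls, and
    fold-enrichment / Z-score / empirical p-value statistics. Includes exonic
    splice enhancer (ESE) masking, exon-region partition analysis, pseudo-ORF
    length null models for noncoding-RNA annotation thresholds, and a
    synthetic multi-exon transcript cohort generator with planted,
    stop-depleted ESE motifs for end-to-end calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
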