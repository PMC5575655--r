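Package: lncfunnel
Title: Discovery, Classification and Co-Expression Analysis of Long
    Non-Coding RNAs in Staged Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide long non-coding RNA
    (lncRNA) analysis from assembled transcripts and read counts across
    developmental stages. Implements the candidate-filtering funnel
    (structural filters, a consensus of coding-potential classifiers built
    on open-reading-frame, Fickett TESTCODE and hexamer-usage features, and
    an expression floor), positional classification into lincRNA, intronic
    and antisense classes, FPKM quantification with gene-level aggregation,
    MA-plot conditional-binomial differential expression with
    Benjamini-Hochberg control, cis-window and sequence-complementarity
    target prediction, lncRNA-gene co-expression network construction, and
    generic functional enrichment over user-supplied term maps. Ships a
    fully labelled synthetic-data generator (toy genome, annotation,
    negative-binomial counts with planted fold-changes and planted
    lncRNA-target correlations) so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    tools,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
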