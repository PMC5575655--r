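#' Predict cis target genes within a genomic window
#'
#' A protein-coding gene is a cis target of a lncRNA when the gap between the
#' gene span and the lncRNA span is at most `window` bp on either side and
#' the spans do not overlap (overlapping genes are excluded). Distances are
#' measured between transcript/gene spans, strand-agnostically.
#'
#' @param lncrnas Tibble of lncRNA spans (`transcript_id`, `chromosome`,
#'   `start`, `end`; internal half-open coordinates), e.g. the `transcripts`
#'   table of a lncRNA [genome_annotation()].
#' @param annotation Reference [genome_annotation()] supplying
#'   protein-coding gene spans.
#' @param window Maximum gap in bp (default 100 kb).
#' @return Tibble with `lncrna_id`, `gene_id`, `mode = "cis"`, `distance`.
#' @export
cis_targets <- function(lncrnas, annotation, window = 100000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (inherits(lncrnas, "genome_annotation")) lncrnas <- lncrnas$transcripts
  genes <- filter(annotation$genes, .data$biotype == "protein_coding")
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) {
    return(tibble(lncrna_id = character(0), gene_id = character(0),
                  mode = character(0), distance = numeric(0)))
  }
  pairs <- inner_join(
    select(lncrnas, lncrna_id = "transcript_id", "chromosome",
           l_start = "start", l_end = "end"),
    select(genes, "gene_id", "chromosome", g_start = "start", g_end = "end"),
    by = "chromosome", relationship = "many-to-many"
  )
  pairs %>%
    mutate(
      overlap = .data$g_start < .data$l_end & .data$l_start < .data$g_end,
      distance = pmax(.data$g_start - .data$l_end,
                      .data$l_start - .data$g_end)
    ) %>%
    filter(!.data$overlap, .data$distance <= window) %>%
    mutate(mode = "cis") %>%
    select("lncrna_id", "gene_id", "mode", "distance") %>%
    arrange(.data$lncrna_id, .data$gene_id)
}

#' Windowed sequence complementarity score
#'
#' Best ungapped base-pairing score between a lncRNA and the reverse
#' complement of an mRNA: every diagonal alignment is scanned with a sliding
#' window and the score is the maximal fraction of complementary positions
#' in any window (1 for a perfectly complementary window). This is a
#' documented proxy for dedicated lncRNA-target hybridisation tools, not a
#' free-energy model.
#'
#' @param lncrna_seq,mrna_seq Nucleotide strings.
#' @param window Window length in nt (capped at the shorter sequence).
#' @return A single numeric score in `[0, 1]`.
#' @export
complementarity_score <- function(lncrna_seq, mrna_seq, window = 100) {
  if (nchar(lncrna_seq) == 0 || nchar(mrna_seq) == 0) {
    abort("complementarity_score: empty sequence")
  }
  rc <- reverse_complement(toupper(mrna_seq))
  cpp_complementarity(toupper(lncrna_seq), rc, as.integer(window))
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence A nucleotide string.
#' @return Its reverse complement (via Biostrings).
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Predict trans target genes by sequence complementarity
#'
#' Scores every lncRNA-mRNA pair with [complementarity_score()] and reports
#' pairs at or above the threshold.
#'
#' @param lncrna_seqs Named character vector of lncRNA sequences.
#' @param mrna_seqs Named character vector of mRNA sequences; names are gene
#'   ids (or map to them via `tx2gene`).
#' @param score_threshold Minimum score (default 0.9).
#' @param window Window length passed to the scorer.
#' @return Tibble with `lncrna_id`, `gene_id`, `mode = "trans"`, `score`.
#' @export
trans_targets <- function(lncrna_seqs, mrna_seqs, score_threshold = 0.9,
                          window = 100) {
  lncrna_seqs <- as_plain_sequences(lncrna_seqs)
  mrna_seqs <- as_plain_sequences(mrna_seqs)
  if (any(nchar(lncrna_seqs) == 0) || any(nchar(mrna_seqs) == 0)) {
    abort("trans_targets: empty sequence")
  }
  rcs <- vapply(mrna_seqs, reverse_complement, character(1))
  out <- purrr::map_dfr(names(lncrna_seqs), function(l) {
    sc <- vapply(rcs, function(rc)
      cpp_complementarity(lncrna_seqs[[l]], rc, as.integer(window)),
      numeric(1))
    tibble(lncrna_id = l, gene_id = names(mrna_seqs), score = unname(sc))
  })
  out %>%
    filter(.data$score >= score_threshold) %>%
    mutate(mode = "trans") %>%
    select("lncrna_id", "gene_id", "mode", "score") %>%
    arrange(.data$lncrna_id, .data$gene_id)
}
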