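#' Structural filter for lncRNA candidates
#'
#' Keeps multi-exon transcripts of at least 200 nt spliced length; shorter or
#' single-exon transcripts are discarded with the reason recorded for the
#' audit table. Boundaries: a transcript of exactly 200 nt is kept.
#'
#' @param transcripts Tibble with at least `transcript_id`,
#'   `spliced_length`, `n_exons` (the `transcripts` table of a
#'   [genome_annotation()]).
#' @param min_length Minimum spliced length in nt.
#' @param min_exons Minimum exon count.
#' @return The input with logical `structural_pass` and character
#'   `structural_reason` (`NA` when passing) columns added.
#' @export
structural_filter <- function(transcripts, min_length = 200, min_exons = 2) {
  transcripts %>%
    mutate(
      structural_reason = case_when(
        .data$spliced_length < min_length & .data$n_exons < min_exons ~
          "too_short;single_exon",
        .data$spliced_length < min_length ~ "too_short",
        .data$n_exons < min_exons ~ "single_exon",
        TRUE ~ NA_character_
      ),
      structural_pass = is.na(.data$structural_reason)
    )
}

#' Intersection consensus over coding-potential methods
#'
#' A transcript is accepted as noncoding only when every enabled method
#' votes noncoding (intersection semantics): one coding vote anywhere
#' removes it.
#'
#' @param votes Tibble of per-method votes (`"coding"`/`"noncoding"`), one
#'   column per method, one row per transcript.
#' @param methods Character vector of enabled vote columns; must be
#'   non-empty and present in `votes`.
#' @return Logical vector, `TRUE` where all enabled methods vote noncoding.
#' @export
consensus_noncoding <- function(votes, methods = names(votes)) {
  if (length(methods) == 0) abort("at least one coding-potential method must be enabled")
  missing_m <- setdiff(methods, names(votes))
  if (length(missing_m) > 0) {
    abort(paste0("unknown vote column(s): ", paste(missing_m, collapse = ", ")))
  }
  vm <- as.matrix(as.data.frame(votes[, methods, drop = FALSE]))
  if (!all(vm %in% c("coding", "noncoding"))) {
    abort("votes must be 'coding' or 'noncoding'")
  }
  rowSums(vm == "noncoding") == length(methods)
}

#' Expression-floor filter
#'
#' Keeps candidates whose maximum FPKM across all samples strictly exceeds
#' the floor (a candidate at exactly the floor is discarded).
#'
#' @param candidate_ids Character vector of transcript ids.
#' @param fpkm An [fpkm_matrix()] (or plain matrix) containing all
#'   candidates as rows.
#' @param floor FPKM floor; default 0.1.
#' @return Tibble with `transcript_id`, `max_fpkm`, `expression_pass`.
#' @export
expression_floor_filter <- function(candidate_ids, fpkm, floor = 0.1) {
  values <- if (inherits(fpkm, "fpkm_matrix")) fpkm$values else fpkm
  missing_f <- setdiff(candidate_ids, rownames(values))
  if (length(missing_f) > 0) {
    abort(paste0("candidate(s) missing from the FPKM matrix: ",
                 paste(head(missing_f, 5), collapse = ", ")))
  }
  mx <- apply(values[candidate_ids, , drop = FALSE], 1, max)
  tibble(transcript_id = candidate_ids, max_fpkm = unname(mx),
         expression_pass = unname(mx) > floor)
}

#' Run the lncRNA discovery funnel
#'
#' Applies the full candidate-filtering funnel to the novel transcripts of an
#' assembled annotation: (1) structural filter (>= 200 nt, >= 2 exons);
#' (2) a consensus of coding-potential classifiers, accepted only when every
#' enabled method votes noncoding; (3) an expression floor
#' (max FPKM > `fpkm_floor` over all samples).
#'
#' Enabled methods: `"orf"` — a longest-ORF length rule (coding when the ORF
#' reaches `orf_coding_min` nt); `"cpat"` — a logistic model on Fickett and
#' hexamer features; `"cnci"` — a logistic model on all four coding-potential
#' features; `"pfam"` — a user-supplied table of protein-domain hits (a hit
#' votes coding). The logistic models are trained on the reference mRNA
#' sequences (coding class) against mononucleotide-shuffled copies of them
#' (noncoding class); hexamer background tables come from the same split.
#'
#' @param annotation Assembled [genome_annotation()] whose `novel`
#'   transcripts are screened.
#' @param sequences Named character vector (or `DNAStringSet`) of spliced
#'   transcript sequences covering all transcripts.
#' @param counts A [count_matrix()] covering all novel transcripts.
#' @param min_length,min_exons Structural thresholds.
#' @param fpkm_floor Expression floor (strict `>`).
#' @param orf_coding_min ORF length (nt) at which the ORF rule votes coding.
#' @param methods Enabled methods among `"orf"`, `"cpat"`, `"cnci"`,
#'   `"pfam"`.
#' @param pfam_hits Optional character vector of transcript ids with a
#'   protein-domain hit (required when `"pfam"` is enabled).
#' @param library_sizes Optional per-sample library sizes for FPKM; defaults
#'   to column sums of `counts`.
#' @param seed Seed for the training shuffle; fixed so discovery is
#'   deterministic given identical inputs.
#' @return A tibble of class `lnc_discovery`, one row per novel transcript,
#'   with all scores, votes, per-stage pass flags and an overall `passed`
#'   plus `reason`. Attributes: `funnel` (stage-by-stage survivor counts)
#'   and `classifiers` (the fitted models).
#' @export
discover_lncrnas <- function(annotation, sequences, counts,
                             min_length = 200, min_exons = 2,
                             fpkm_floor = 0.1, orf_coding_min = 300,
                             methods = c("orf", "cpat", "cnci"),
                             pfam_hits = NULL,
                             library_sizes = NULL,
                             seed = 1L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (length(methods) == 0) {
    abort("at least one coding-potential method must be enabled")
  }
  if ("pfam" %in% methods && is.null(pfam_hits)) {
    abort("method 'pfam' enabled but no pfam_hits table supplied")
  }
  sequences <- as_plain_sequences(sequences)

  novel <- filter(annotation$transcripts, .data$biotype == "novel")
  if (nrow(novel) == 0) abort("annotation contains no novel transcripts")
  missing_seq <- setdiff(novel$transcript_id, names(sequences))
  if (length(missing_seq) > 0) {
    abort(paste0("missing sequence for transcript(s): ",
                 paste(head(missing_seq, 5), collapse = ", ")))
  }

  out <- structural_filter(novel, min_length = min_length,
                           min_exons = min_exons)
  surv_structural <- out$transcript_id[out$structural_pass]

  # train the classifiers on reference mRNAs vs their shuffles
  ref_ids <- filter(annotation$transcripts,
                    .data$biotype == "known_mRNA")$transcript_id
  ref_ids <- intersect(ref_ids, names(sequences))
  if (length(ref_ids) < 20) {
    abort("need at least 20 reference mRNA sequences to train the classifiers")
  }
  coding_seqs <- sequences[ref_ids]
  noncoding_seqs <- withr::with_seed(seed, shuffle_sequences(coding_seqs))
  names(noncoding_seqs) <- paste0(ref_ids, "_shuf")
  cod_hex <- build_hexamer_table(coding_seqs)
  non_hex <- build_hexamer_table(noncoding_seqs)
  train_feats <- coding_features(c(coding_seqs, noncoding_seqs),
                                 cod_hex, non_hex)
  train_labels <- rep(c("coding", "noncoding"),
                      c(length(coding_seqs), length(noncoding_seqs)))
  cnci_model <- train_coding_classifier(train_feats, train_labels)
  cpat_model <- train_coding_classifier(train_feats, train_labels,
                                        feature_names = c("fickett", "hexamer"))

  feats <- coding_features(sequences[out$transcript_id], cod_hex, non_hex)
  out <- left_join(out, feats, by = "transcript_id")
  out$vote_orf <- if_else(out$orf_length >= orf_coding_min,
                          "coding", "noncoding")
  out$vote_cpat <- predict(cpat_model, out)$vote
  out$vote_cnci <- predict(cnci_model, out)$vote
  if (!is.null(pfam_hits)) {
    out$vote_pfam <- if_else(out$transcript_id %in% pfam_hits,
                             "coding", "noncoding")
  }
  vote_cols <- paste0("vote_", methods)
  out$consensus_noncoding <- consensus_noncoding(out, vote_cols)
  surv_coding <- out$transcript_id[out$structural_pass &
                                     out$consensus_noncoding]

  fpkm <- compute_fpkm(counts,
                       lengths = setNames(annotation$transcripts$spliced_length,
                                          annotation$transcripts$transcript_id),
                       library_sizes = library_sizes)
  expr <- expression_floor_filter(out$transcript_id, fpkm, floor = fpkm_floor)
  out <- left_join(out, expr, by = "transcript_id")

  out <- out %>%
    mutate(
      passed = .data$structural_pass & .data$consensus_noncoding &
        .data$expression_pass,
      reason = case_when(
        !.data$structural_pass ~ .data$structural_reason,
        !.data$consensus_noncoding ~ "voted_coding",
        !.data$expression_pass ~ "below_expression_floor",
        TRUE ~ NA_character_
      )
    )

  funnel <- tibble(
    stage = c("novel", "structural", "coding_consensus", "expression_floor"),
    n = c(nrow(out), length(surv_structural), length(surv_coding),
          sum(out$passed))
  )
  attr(out, "funnel") <- funnel
  attr(out, "classifiers") <- list(cnci = cnci_model, cpat = cpat_model)
  class(out) <- c("lnc_discovery", class(out))
  out
}

#' Funnel survivor counts of a discovery run
#'
#' @param discovery The result of [discover_lncrnas()].
#' @return Tibble with `stage` and surviving count `n`.
#' @export
discovery_funnel <- function(discovery) {
  f <- attr(discovery, "funnel")
  if (is.null(f)) abort("no funnel attribute; not a discovery result?")
  f
}

as_plain_sequences <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (!is.character(sequences) || is.null(names(sequences))) {
    abort("sequences must be a named character vector or DNAStringSet")
  }
  toupper(sequences)
}
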