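#' FPKM expression matrix
#'
#' @param values Non-negative numeric matrix (features x samples).
#' @param samples Sample metadata tibble (`sample`, `stage`, `replicate`).
#' @param feature_kind `"transcript"`, `"gene"` or `"lncRNA"`.
#' @return An object of class `fpkm_matrix`.
#' @export
fpkm_matrix <- function(values, samples, feature_kind = "transcript") {
  if (any(values < 0)) abort("FPKM values must be non-negative")
  samples <- as_tibble(samples)
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(samples)) {
      abort("value columns do not match the sample metadata")
    }
    colnames(values) <- samples$sample
  }
  stopifnot(all(colnames(values) == samples$sample))
  structure(list(values = values, samples = samples,
                 feature_kind = feature_kind),
            class = "fpkm_matrix")
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat("<fpkm_matrix> ", nrow(x$values), " ", x$feature_kind, "s x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Long-format view of an FPKM matrix
#'
#' @param x An `fpkm_matrix`.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `sample`, `stage`, `replicate`, `fpkm`.
#' @export
tidy.fpkm_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "feature_id") %>%
    tidyr::pivot_longer(-"feature_id", names_to = "sample",
                        values_to = "fpkm") %>%
    left_join(x$samples, by = "sample")
}

#' Compute FPKM from counts
#'
#' `FPKM = count / (length/1e3) / (library_size/1e6)`. The library size is
#' the per-sample total of mapped fragments; by default the column sum of the
#' count matrix, overridable with externally determined totals. FPKM is
#' always computed here from integer counts — it is never read in — so this
#' operation is the single quantification authority of the pipeline.
#'
#' @param counts A [count_matrix()].
#' @param lengths Named vector of spliced lengths (nt) covering all features.
#' @param library_sizes Optional named (or ordered) per-sample totals;
#'   default `colSums(counts)`.
#' @return An [fpkm_matrix()] at transcript level.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  feats <- rownames(counts$counts)
  missing_l <- setdiff(feats, names(lengths))
  if (length(missing_l) > 0) {
    abort(paste0("missing spliced length for feature(s): ",
                 paste(head(missing_l, 5), collapse = ", ")))
  }
  len <- as.numeric(lengths[feats])
  if (any(len <= 0)) abort("feature lengths must be positive")
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts$counts)
  } else if (!is.null(names(library_sizes))) {
    library_sizes <- library_sizes[colnames(counts$counts)]
  }
  if (any(is.na(library_sizes)) || any(library_sizes <= 0)) {
    abort("library sizes must be positive for every sample")
  }
  vals <- sweep(counts$counts / (len / 1e3), 2, library_sizes / 1e6, "/")
  fpkm_matrix(vals, counts$samples, feature_kind = "transcript")
}

#' Aggregate transcript FPKM to gene level
#'
#' The gene's FPKM in each sample is the sum of its transcripts' FPKM
#' (additive under a shared per-sample normaliser, so per-sample totals are
#' conserved).
#'
#' @param transcript_fpkm An [fpkm_matrix()] at transcript level.
#' @param tx2gene Tibble with `transcript_id`, `gene_id` covering every
#'   transcript row; a transcript mapped to two genes is an error.
#' @return An [fpkm_matrix()] at gene level.
#' @export
gene_level_fpkm <- function(transcript_fpkm, tx2gene) {
  stopifnot(inherits(transcript_fpkm, "fpkm_matrix"))
  tx2gene <- distinct(as_tibble(tx2gene), .data$transcript_id, .data$gene_id)
  dup <- tx2gene %>% dplyr::count(.data$transcript_id) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("transcript(s) mapped to more than one gene: ",
                 paste(head(dup$transcript_id, 5), collapse = ", ")))
  }
  feats <- rownames(transcript_fpkm$values)
  map <- setNames(tx2gene$gene_id, tx2gene$transcript_id)[feats]
  if (anyNA(map)) {
    abort(paste0("transcript(s) missing from tx2gene map: ",
                 paste(head(feats[is.na(map)], 5), collapse = ", ")))
  }
  agg <- rowsum(transcript_fpkm$values, group = map)
  fpkm_matrix(agg[order(rownames(agg)), , drop = FALSE],
              transcript_fpkm$samples, feature_kind = "gene")
}

#' Between-replicate Pearson correlation within a stage
#'
#' Computed on `log10(FPKM + 1)`-transformed values. A zero-variance
#' replicate yields `NA` correlations with a warning.
#'
#' @param fpkm An [fpkm_matrix()].
#' @param stage Stage label.
#' @return Symmetric replicate x replicate correlation matrix with unit
#'   diagonal.
#' @export
replicate_correlation <- function(fpkm, stage) {
  stopifnot(inherits(fpkm, "fpkm_matrix"))
  cols <- fpkm$samples$sample[fpkm$samples$stage == stage]
  if (length(cols) < 2) abort(paste0("stage '", stage, "' has < 2 replicates"))
  x <- log10(fpkm$values[, cols, drop = FALSE] + 1)
  zero_var <- apply(x, 2, sd) == 0
  if (any(zero_var)) {
    warn(paste0("zero-variance replicate(s): ",
                paste(cols[zero_var], collapse = ", "),
                "; correlations reported as NA"))
  }
  suppressWarnings(r <- cor(x))
  diag(r) <- 1
  r
}

#' Stage-specific expression
#'
#' A feature is expressed in a stage when its mean FPKM over that stage's
#' replicates strictly exceeds `expressed_floor`, and stage-specific when it
#' is expressed in exactly one stage. The reported fraction is taken over
#' features expressed in at least one stage.
#'
#' @param fpkm An [fpkm_matrix()].
#' @param expressed_floor Stage-mean FPKM floor.
#' @return Tibble with `feature_id`, `expressed_stages`
#'   (comma-joined), `n_stages`, `specific_stage` (`NA` unless expressed in
#'   exactly one stage); attribute `fraction_specific`.
#' @export
stage_specific_features <- function(fpkm, expressed_floor = 0.1) {
  stopifnot(inherits(fpkm, "fpkm_matrix"))
  stages <- unique(fpkm$samples$stage)
  means <- sapply(stages, function(st) {
    cols <- fpkm$samples$sample[fpkm$samples$stage == st]
    rowMeans(fpkm$values[, cols, drop = FALSE])
  })
  expressed <- means > expressed_floor
  n_stages <- unname(rowSums(expressed))
  specific <- ifelse(n_stages == 1,
                     stages[apply(expressed, 1, which.max)], NA_character_)
  specific <- unname(specific)
  out <- tibble(
    feature_id = rownames(fpkm$values),
    expressed_stages = apply(expressed, 1, function(e)
      paste(stages[e], collapse = ",")),
    n_stages = as.integer(n_stages),
    specific_stage = specific
  )
  n_expr <- sum(n_stages >= 1)
  attr(out, "fraction_specific") <-
    if (n_expr == 0) NA_real_ else sum(n_stages == 1) / n_expr
  out
}

#' Fraction of expressed features specific to one stage
#'
#' @param specificity Result of [stage_specific_features()].
#' @return A single numeric fraction.
#' @export
stage_specific_fraction <- function(specificity) {
  attr(specificity, "fraction_specific")
}
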