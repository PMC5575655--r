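#' MA-plot conditional-binomial z statistic
#'
#' The random-sampling model behind MA-plot differential expression of two
#' count libraries: under the null, the count in library 1 conditioned on the
#' pooled total is Binomial(k1 + k2, q) with q = n1 / (n1 + n2), where n1 and
#' n2 are the library totals. The statistic is the normal approximation
#' `z = (k1 - (k1+k2) q) / sqrt((k1+k2) q (1-q))`, with a two-sided p-value.
#' A pooled total of zero returns z = 0, p = 1 by convention.
#'
#' @param k1,k2 Pooled counts of the feature in the two groups (vectors ok).
#' @param n1,n2 Library totals of the two groups.
#' @return Tibble with `z` and `p`.
#' @export
mars_z <- function(k1, k2, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("library totals must be positive")
  if (any(k1 < 0) || any(k2 < 0)) abort("counts must be non-negative")
  q <- n1 / (n1 + n2)
  total <- k1 + k2
  z <- ifelse(total == 0, 0,
              (k1 - total * q) / sqrt(total * q * (1 - q)))
  p <- ifelse(total == 0, 1, 2 * pnorm(-abs(z)))
  tibble(z = z, p = pmin(p, 1))
}

#' Log2 fold change of stage-mean FPKM
#'
#' `log2((experiment + pseudocount) / (control + pseudocount))`; the
#' pseudocount keeps stage-specific features finite.
#'
#' @param mean_experiment,mean_control Non-negative stage means.
#' @param pseudocount Added to both means.
#' @return Numeric log2 fold change(s).
#' @export
log2_fold_change <- function(mean_experiment, mean_control, pseudocount = 0.01) {
  if (any(mean_experiment < 0) || any(mean_control < 0)) {
    abort("means must be non-negative")
  }
  if (pseudocount == 0 && (any(mean_experiment == 0) || any(mean_control == 0))) {
    warn("zero mean with zero pseudocount yields infinite fold change")
  }
  log2((mean_experiment + pseudocount) / (mean_control + pseudocount))
}

#' Benjamini-Hochberg FDR
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation;
#' order-preserving and monotone, and never below the raw p-value.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differential expression
#'
#' `up` when fdr < `fdr_cut` and log2fc > `lfc_cut`; `down` when fdr <
#' `fdr_cut` and log2fc < -`lfc_cut`; otherwise `ns`. Both cuts are strict.
#'
#' @param fdr,log2fc Vectors of equal length.
#' @param fdr_cut,lfc_cut Thresholds (defaults 0.05 and 1).
#' @return Character vector of calls.
#' @export
call_de <- function(fdr, log2fc, fdr_cut = 0.05, lfc_cut = 1) {
  case_when(
    fdr < fdr_cut & log2fc > lfc_cut ~ "up",
    fdr < fdr_cut & log2fc < -lfc_cut ~ "down",
    TRUE ~ "ns"
  )
}

#' Pairwise differential-expression test across stages
#'
#' For each contrast, replicate counts are pooled within stage, the
#' conditional-binomial z statistic is computed per feature against the
#' pooled library totals, fold change is taken on stage-mean FPKM (with
#' pseudocount), and BH correction is applied within the contrast. Contrast
#' labels are `control_vs_experiment`; log2 fold change is experiment over
#' control, so `up` means higher in the later (experiment) stage.
#'
#' @param counts A [count_matrix()].
#' @param fpkm An [fpkm_matrix()] over the same features (used for fold
#'   change); defaults to FPKM computed from `counts` with `lengths`.
#' @param contrasts List of `c(control, experiment)` stage pairs; default
#'   the three stage contrasts fetus/lamb, lamb/adult, fetus/adult.
#' @param fdr_cut,lfc_cut Calling thresholds.
#' @param pseudocount Fold-change pseudocount.
#' @return Tibble with `feature_id`, `contrast`, `log2fc`, `z`, `p`, `fdr`,
#'   `call`.
#' @export
de_test <- function(counts, fpkm,
                    contrasts = list(c("fetus", "lamb"),
                                     c("lamb", "adult"),
                                     c("fetus", "adult")),
                    fdr_cut = 0.05, lfc_cut = 1, pseudocount = 0.01) {
  stopifnot(inherits(counts, "count_matrix"), inherits(fpkm, "fpkm_matrix"))
  if (!identical(sort(rownames(counts$counts)), sort(rownames(fpkm$values)))) {
    abort("counts and fpkm must cover the same features")
  }
  purrr::map_dfr(contrasts, function(ct) {
    ctrl <- ct[1]; expt <- ct[2]
    c_ctrl <- counts$samples$sample[counts$samples$stage == ctrl]
    c_expt <- counts$samples$sample[counts$samples$stage == expt]
    if (length(c_ctrl) == 0 || length(c_expt) == 0) {
      abort(paste0("contrast ", ctrl, "_vs_", expt, ": missing stage samples"))
    }
    k_expt <- rowSums(counts$counts[, c_expt, drop = FALSE])
    k_ctrl <- rowSums(counts$counts[, c_ctrl, drop = FALSE])
    n_expt <- sum(counts$counts[, c_expt, drop = FALSE])
    n_ctrl <- sum(counts$counts[, c_ctrl, drop = FALSE])
    zt <- mars_z(k_expt, k_ctrl, n_expt, n_ctrl)
    f_expt <- rowMeans(fpkm$values[rownames(counts$counts), c_expt, drop = FALSE])
    f_ctrl <- rowMeans(fpkm$values[rownames(counts$counts), c_ctrl, drop = FALSE])
    lfc <- log2_fold_change(f_expt, f_ctrl, pseudocount = pseudocount)
    fdr <- bh_fdr(zt$p)
    tibble(
      feature_id = rownames(counts$counts),
      contrast = paste0(ctrl, "_vs_", expt),
      log2fc = unname(lfc), z = zt$z, p = zt$p, fdr = fdr,
      call = call_de(fdr, lfc, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
    )
  })
}

#' Three-set Venn partition
#'
#' Standard inclusion partition of three feature sets into seven regions:
#' each set's exclusive members, the three pairwise-only intersections, and
#' the triple intersection.
#'
#' @param de_sets Named list of three character vectors.
#' @return Tibble with `region` and `n`; region names use the list names.
#' @export
venn_partition <- function(de_sets) {
  if (length(de_sets) != 3 || is.null(names(de_sets))) {
    abort("venn_partition needs a named list of exactly three sets")
  }
  nm <- names(de_sets)
  a <- unique(de_sets[[1]]); b <- unique(de_sets[[2]]); c <- unique(de_sets[[3]])
  abc <- intersect(intersect(a, b), c)
  ab <- setdiff(intersect(a, b), abc)
  ac <- setdiff(intersect(a, c), abc)
  bc <- setdiff(intersect(b, c), abc)
  a_only <- setdiff(a, union(b, c))
  b_only <- setdiff(b, union(a, c))
  c_only <- setdiff(c, union(a, b))
  tibble(
    region = c(paste0(nm, "_only"),
               paste(nm[1], nm[2], sep = "&"),
               paste(nm[1], nm[3], sep = "&"),
               paste(nm[2], nm[3], sep = "&"),
               paste(nm, collapse = "&")),
    n = c(length(a_only), length(b_only), length(c_only),
          length(ab), length(ac), length(bc), length(abc))
  )
}

#' Hierarchically cluster differentially expressed features
#'
#' Rows are z-scored, distance is `1 - Pearson` between rows, linkage is
#' average (UPGMA). Zero-variance rows are dropped with a warning. Rows are
#' pre-sorted by feature id so the result is deterministic, with ties broken
#' by id order.
#'
#' @param values Numeric matrix (features x samples) restricted to the
#'   features of interest, with rownames.
#' @return List with the `hclust` object (`tree`) and the leaf ordering
#'   (`leaves`, feature ids in dendrogram order).
#' @export
hierarchical_cluster <- function(values) {
  if (is.null(rownames(values))) abort("matrix needs feature rownames")
  if (nrow(values) < 2) abort("need at least 2 features to cluster")
  values <- values[order(rownames(values)), , drop = FALSE]
  v <- apply(values, 1, sd)
  if (any(v == 0)) {
    warn(paste0("dropping zero-variance feature(s): ",
                paste(head(rownames(values)[v == 0], 5), collapse = ", ")))
    values <- values[v > 0, , drop = FALSE]
    if (nrow(values) < 2) abort("fewer than 2 features left after dropping")
  }
  z <- t(scale(t(values)))
  d <- as.dist(1 - cor(t(z)))
  tree <- hclust(d, method = "average")
  list(tree = tree, leaves = tree$labels[tree$order])
}
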