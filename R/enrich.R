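#' Hypergeometric term enrichment
#'
#' Classic over-representation analysis: for each term, the upper-tail
#' hypergeometric probability of drawing at least `k` term genes in a set of
#' size `n` from a universe of `N` genes of which `K` are in the term,
#' followed by Benjamini-Hochberg correction across terms. A term is
#' significant when the corrected p-value is at or below `alpha`.
#'
#' @param gene_set Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector of background genes.
#' @param term2gene Tibble with `term_id`, `term_name`, `gene_id`.
#' @param alpha Significance cut on corrected p (default 0.05, inclusive).
#' @return Tibble with `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`,
#'   `p_corrected`, `significant`, sorted by `p_corrected` then `term_id`.
#' @export
hypergeometric_enrichment <- function(gene_set, universe, term2gene,
                                      alpha = 0.05) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  stray <- setdiff(gene_set, universe)
  if (length(stray) > 0) {
    abort(paste0("gene set members missing from the universe: ",
                 paste(head(stray, 10), collapse = ", ")))
  }
  if (nrow(term2gene) == 0) abort("term map is empty")
  t2g <- term2gene %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$term_id, .data$term_name, .data$gene_id)
  n <- length(gene_set)
  N <- length(universe)
  out <- t2g %>%
    group_by(.data$term_id, .data$term_name) %>%
    summarise(k = sum(.data$gene_id %in% gene_set), K = dplyr::n(),
              .groups = "drop") %>%
    mutate(n = n, N = N,
           p = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                      lower.tail = FALSE))
  out %>%
    mutate(p_corrected = bh_fdr(.data$p),
           significant = .data$p_corrected <= alpha) %>%
    arrange(.data$p_corrected, .data$term_id)
}

#' Score-based (Kolmogorov-Smirnov) term enrichment
#'
#' Two-sample KS test of the term genes' scores against the non-term genes'
#' scores, per term. Terms with fewer than two genes in the universe are
#' skipped with a warning. A term is significant at `ks_p <= alpha`.
#'
#' @param gene_scores Named numeric vector: one score (e.g. a DE p-value)
#'   per universe gene.
#' @param term2gene Tibble with `term_id`, `term_name`, `gene_id`.
#' @param alpha Significance cut (default 0.05, inclusive).
#' @return Tibble with `term_id`, `term_name`, `n_term`, `D`, `ks_p`,
#'   `significant`.
#' @export
ks_enrichment <- function(gene_scores, term2gene, alpha = 0.05) {
  if (is.null(names(gene_scores))) abort("gene_scores must be named by gene")
  universe <- names(gene_scores)
  t2g <- term2gene %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$term_id, .data$term_name, .data$gene_id)
  terms <- distinct(t2g, .data$term_id, .data$term_name)
  small <- t2g %>%
    dplyr::count(.data$term_id) %>%
    filter(.data$n < 2) %>%
    pull(.data$term_id)
  if (length(small) > 0) {
    warn(paste0("skipping term(s) with < 2 universe genes: ",
                paste(head(small, 5), collapse = ", ")))
    terms <- filter(terms, !.data$term_id %in% small)
  }
  purrr::map_dfr(seq_len(nrow(terms)), function(i) {
    tid <- terms$term_id[i]
    in_term <- unique(t2g$gene_id[t2g$term_id == tid])
    x <- gene_scores[in_term]
    y <- gene_scores[setdiff(universe, in_term)]
    if (length(y) < 2) {
      return(tibble(term_id = tid, term_name = terms$term_name[i],
                    n_term = length(in_term), D = 0, ks_p = 1,
                    significant = FALSE))
    }
    kt <- suppressWarnings(ks.test(x, y))  # ties are expected in p-value scores
    tibble(term_id = tid, term_name = terms$term_name[i],
           n_term = length(in_term), D = unname(kt$statistic),
           ks_p = kt$p.value, significant = kt$p.value <= alpha)
  })
}

#' Top enriched terms
#'
#' Stable sort on the chosen column with `term_id` as tie-break, truncated
#' at `n`.
#'
#' @param results Enrichment result tibble.
#' @param n Number of terms to keep (default 20).
#' @param order_by Column to rank by (default `"p_corrected"`).
#' @return The top rows.
#' @export
top_terms <- function(results, n = 20, order_by = "p_corrected") {
  if (!order_by %in% names(results)) {
    abort(paste0("no column '", order_by, "' in results"))
  }
  results %>%
    arrange(.data[[order_by]], .data$term_id) %>%
    slice_head(n = n)
}

#' Functional-category breakdown of gene sets
#'
#' Counts and proportions per category for each gene set; genes without a
#' category are counted under `"unannotated"`, so per-set proportions sum
#' to 1. An empty gene set yields a single all-zero row.
#'
#' @param gene_sets Named list of character vectors (e.g. target genes per
#'   contrast).
#' @param category_map Tibble with `gene_id`, `category`.
#' @return Tibble with `set`, `category`, `n`, `proportion`.
#' @export
category_breakdown <- function(gene_sets, category_map) {
  if (is.null(names(gene_sets))) abort("gene_sets must be a named list")
  map <- distinct(as_tibble(category_map), .data$gene_id, .data$category)
  purrr::imap_dfr(gene_sets, function(genes, set_name) {
    genes <- unique(genes)
    if (length(genes) == 0) {
      return(tibble(set = set_name, category = "unannotated",
                    n = 0L, proportion = 0))
    }
    tibble(gene_id = genes) %>%
      left_join(map, by = "gene_id", relationship = "many-to-many") %>%
      mutate(category = dplyr::coalesce(.data$category, "unannotated")) %>%
      distinct(.data$gene_id, .data$category) %>%
      dplyr::count(.data$category, name = "n") %>%
      mutate(set = set_name, proportion = .data$n / sum(.data$n)) %>%
      select("set", "category", "n", "proportion")
  })
}
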