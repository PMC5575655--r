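new_coexpression_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Edge table of a co-expression network
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return The edge tibble with endpoint attributes joined in.
#' @export
tidy.coexpression_network <- function(x, ...) {
  x$edges %>%
    left_join(rename(x$nodes, lncrna_id = "id",
                     lncrna_regulation = "regulation") %>% select(-"kind"),
              by = "lncrna_id") %>%
    left_join(rename(x$nodes, gene_id = "id",
                     gene_regulation = "regulation") %>% select(-"kind"),
              by = "gene_id")
}

#' Screen target pairs by co-expression
#'
#' For every candidate lncRNA-gene pair, the Pearson correlation of
#' `log10(FPKM + 1)` profiles across the samples is computed, with a p-value
#' from the t-test of r on n - 2 degrees of freedom. An edge passes when
#' `r > r_cut` (signed; set `use_abs = TRUE` for absolute-value screening)
#' and `p < p_cut`. Pairs with a zero-variance profile fail with the reason
#' recorded.
#'
#' @param pairs Tibble with `lncrna_id`, `gene_id`, `mode` (cis/trans) and
#'   optional evidence columns.
#' @param lnc_fpkm,gene_fpkm [fpkm_matrix()] objects over the same samples.
#' @param r_cut Correlation threshold (strict `>`), default 0.8.
#' @param p_cut P-value threshold (strict `<`), default 0.05.
#' @param use_abs Screen on `|r|` instead of signed r.
#' @return The pair table with `r`, `p`, `passes`, `fail_reason` added.
#' @export
coexpression_screen <- function(pairs, lnc_fpkm, gene_fpkm,
                                r_cut = 0.8, p_cut = 0.05, use_abs = FALSE) {
  stopifnot(inherits(lnc_fpkm, "fpkm_matrix"), inherits(gene_fpkm, "fpkm_matrix"))
  if (!identical(lnc_fpkm$samples$sample, gene_fpkm$samples$sample)) {
    abort("lncRNA and gene FPKM matrices must share the same samples")
  }
  lv <- log10(lnc_fpkm$values + 1)
  gv <- log10(gene_fpkm$values + 1)
  missing_l <- setdiff(unique(pairs$lncrna_id), rownames(lv))
  missing_g <- setdiff(unique(pairs$gene_id), rownames(gv))
  if (length(missing_l) > 0 || length(missing_g) > 0) {
    abort(paste0("pair endpoint(s) missing from FPKM: ",
                 paste(head(c(missing_l, missing_g), 5), collapse = ", ")))
  }
  res <- purrr::map2_dfr(pairs$lncrna_id, pairs$gene_id, function(l, g) {
    x <- lv[l, ]; y <- gv[g, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(r = NA_real_, p = NA_real_, fail_reason = "zero_variance"))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(r = unname(ct$estimate), p = ct$p.value,
           fail_reason = NA_character_)
  })
  out <- bind_cols(pairs, res)
  r_eff <- if (use_abs) abs(out$r) else out$r
  out %>%
    mutate(
      passes = !is.na(.data$r) & r_eff > r_cut & .data$p < p_cut,
      fail_reason = case_when(
        !is.na(.data$fail_reason) ~ .data$fail_reason,
        .data$passes ~ NA_character_,
        TRUE ~ "below_threshold"
      )
    )
}

#' Build a lncRNA-gene co-expression network
#'
#' Nodes carry their kind (lncRNA or gene) and regulation direction taken
#' from the differential-expression calls; edges carry the prediction mode
#' (cis, drawn solid in the figures; trans, dashed), correlation and
#' p-value. An endpoint without a DE call is an error.
#'
#' @param edges Passing rows of [coexpression_screen()].
#' @param de_calls Tibble with `feature_id` and `call` covering every
#'   endpoint (typically one contrast's slice of [de_test()]).
#' @return A `coexpression_network`.
#' @export
build_network <- function(edges, de_calls) {
  edges <- filter(edges, .data$passes)
  ids <- unique(c(edges$lncrna_id, edges$gene_id))
  calls <- setNames(de_calls$call, de_calls$feature_id)
  missing_ids <- ids[!ids %in% names(calls)]
  if (length(missing_ids) > 0) {
    abort(paste0("network endpoint(s) without a DE call: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  nodes <- tibble(
    id = ids,
    kind = if_else(ids %in% edges$lncrna_id, "lncRNA", "gene"),
    regulation = unname(calls[ids])
  )
  new_coexpression_network(
    nodes,
    select(edges, "lncrna_id", "gene_id", "mode", "r", "p")
  )
}

#' Extract the keyword (e.g. muscle-related) subnetwork
#'
#' Keeps edges whose gene endpoint is annotated with at least one term whose
#' name contains at least one keyword (case-insensitive substring match),
#' together with the incident lncRNAs.
#'
#' @param network A `coexpression_network`.
#' @param term_annotations Tibble with `gene_id`, `term_name`.
#' @param keywords Character vector of keywords; defaults to the muscle
#'   development set.
#' @return A `coexpression_network` whose edge set is a subset of the input.
#' @export
keyword_subnetwork <- function(network, term_annotations,
                               keywords = c("myoblast", "muscle development",
                                            "skeletal development")) {
  stopifnot(inherits(network, "coexpression_network"))
  if (length(keywords) == 0) abort("need at least one keyword")
  kw <- stringr::str_to_lower(keywords)
  tn <- stringr::str_to_lower(term_annotations$term_name)
  hit_row <- purrr::map_lgl(tn, function(x)
    any(vapply(kw, function(k) grepl(k, x, fixed = TRUE), logical(1))))
  hits <- unique(term_annotations$gene_id[hit_row])
  edges <- filter(network$edges, .data$gene_id %in% hits)
  keep_ids <- unique(c(edges$lncrna_id, edges$gene_id))
  new_coexpression_network(
    filter(network$nodes, .data$id %in% keep_ids),
    edges
  )
}
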