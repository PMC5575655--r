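#' Plot the discovery funnel
#'
#' Survivor counts at each stage of the candidate-filtering funnel.
#'
#' @param discovery Result of [discover_lncrnas()] (or its funnel tibble).
#' @return A ggplot object.
#' @export
plot_funnel <- function(discovery) {
  funnel <- if (inherits(discovery, "lnc_discovery")) {
    discovery_funnel(discovery)
  } else {
    discovery
  }
  funnel$stage <- factor(funnel$stage, levels = funnel$stage)
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "transcripts surviving",
                  title = "lncRNA discovery funnel") +
    ggplot2::theme_minimal()
}

#' Plot positional class proportions
#'
#' @param classified Result of [classify_position()] (or a
#'   [class_proportions()] table).
#' @return A ggplot object.
#' @export
plot_class_proportions <- function(classified) {
  cp <- if ("percent" %in% names(classified)) classified
        else class_proportions(classified)
  ggplot2::ggplot(cp, ggplot2::aes(x = .data$positional_class, y = .data$n,
                                   fill = .data$positional_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "lncRNAs", title = "Positional classes") +
    ggplot2::theme_minimal()
}

#' Chromosome distribution of features against genome-size share
#'
#' @param dist_tbl Result of [chromosome_distribution()].
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(dist_tbl) {
  long <- tidyr::pivot_longer(dist_tbl, c("feature_share", "size_share"),
                              names_to = "share", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chromosome, y = .data$value,
                                     group = .data$share,
                                     colour = .data$share)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "share",
                  title = "Feature vs chromosome-size share") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a differential-expression table
#'
#' Log2 fold change against the z statistic's underlying abundance proxy
#' (pooled significance), coloured by call.
#'
#' @param de Tibble from [de_test()] (optionally one contrast).
#' @return A ggplot object.
#' @export
plot_ma <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$z, y = .data$log2fc,
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", ns = "grey70")) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "conditional-binomial z", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot a lncRNA-gene co-expression network
#'
#' Genes and lncRNAs in the conventional colours, regulation direction as
#' point shape (triangle up / circle down), cis edges solid and trans edges
#' dashed.
#'
#' @param network A `coexpression_network`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_coexpression_network <- function(network, seed = 1L) {
  stopifnot(inherits(network, "coexpression_network"))
  g <- as_igraph(network)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- network$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  pos <- setNames(seq_len(nrow(nodes)), nodes$id)
  edges <- network$edges
  edges$x <- nodes$x[pos[edges$lncrna_id]]
  edges$y <- nodes$y[pos[edges$lncrna_id]]
  edges$xend <- nodes$x[pos[edges$gene_id]]
  edges$yend <- nodes$y[pos[edges$gene_id]]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$mode),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind,
                   shape = .data$regulation), size = 3) +
    ggplot2::scale_colour_manual(values = c(gene = "purple",
                                            lncRNA = "darkgreen")) +
    ggplot2::scale_shape_manual(values = c(up = 17, down = 16, ns = 15)) +
    ggplot2::scale_linetype_manual(values = c(cis = "solid",
                                              trans = "dashed")) +
    ggplot2::theme_void()
}
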