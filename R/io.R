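#' Build a validated count matrix
#'
#' @param counts Integer matrix (features x samples) with rownames and
#'   colnames, or a data frame with a first column of feature ids.
#' @param samples Tibble with columns `sample`, `stage` (one of `"fetus"`,
#'   `"lamb"`, `"adult"`) and `replicate` covering every column of `counts`.
#' @return An object of class `count_matrix`: list with integer matrix
#'   `counts` and tibble `samples`.
#' @export
count_matrix <- function(counts, samples) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count matrix needs feature rownames and sample colnames")
  }
  if (any(is.na(counts))) abort("count matrix contains missing values")
  if (any(counts < 0)) abort("negative count encountered")
  if (any(counts != round(counts))) abort("non-integer count encountered")
  storage.mode(counts) <- "integer"

  samples <- as_tibble(samples)
  if (!all(c("sample", "stage", "replicate") %in% names(samples))) {
    abort("sample metadata needs columns sample, stage, replicate")
  }
  samples$sample <- as.character(samples$sample)
  unlabelled <- setdiff(colnames(counts), samples$sample)
  if (length(unlabelled) > 0) {
    abort(paste0("sample column(s) without metadata: ",
                 paste(unlabelled, collapse = ", ")))
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  valid_stages <- c("fetus", "lamb", "adult")
  if (!all(samples$stage %in% valid_stages)) {
    abort(paste0("stage labels must be one of: ",
                 paste(valid_stages, collapse = ", ")))
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples\n", sep = "")
  st <- table(x$samples$stage)
  cat("  stages:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a count table and its sample metadata
#'
#' @param path TSV with a first column of feature ids and one integer column
#'   per sample.
#' @param meta_path TSV with columns `sample`, `stage`, `replicate`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  count_matrix(tab, meta)
}

#' Read a term-to-gene map
#'
#' @param path TSV with columns `term_id`, `term_name`, `gene_id` (one row
#'   per membership).
#' @return Tibble with those three character columns.
#' @export
read_term_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("term_id", "term_name", "gene_id") %in% names(tab))) {
    abort("term map needs columns term_id, term_name, gene_id")
  }
  mutate(tab, across(all_of(c("term_id", "term_name", "gene_id")), as.character))
}

#' Write a co-expression network
#'
#' Persists node attributes (kind, regulation direction) and edge attributes
#' (mode cis/trans, correlation r, p) in one of three formats. SIF uses the
#' edge mode as the relation string; GraphML goes through igraph and
#' round-trips all attributes; the TSV format is a flat edge table.
#'
#' @param network A `coexpression_network` (see [build_network()]).
#' @param path Output path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "coexpression_network"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort(paste0("cannot write network: directory does not exist: ",
                            dirname(path)))
  edges <- network$edges
  nodes <- network$nodes
  if (format == "sif") {
    lines <- if (nrow(edges) == 0) character(0) else
      paste(edges$lncrna_id, edges$mode, edges$gene_id, sep = "\t")
    writeLines(lines, path)
  } else if (format == "tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a co-expression network to an igraph object
#'
#' @param network A `coexpression_network`.
#' @return An igraph graph with node attributes `kind`, `regulation` and
#'   edge attributes `mode`, `r`, `p`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  edges <- network$edges
  el <- data.frame(from = edges$lncrna_id, to = edges$gene_id,
                   mode = edges$mode, r = edges$r, p = edges$p,
                   stringsAsFactors = FALSE)
  vx <- data.frame(name = network$nodes$id, kind = network$nodes$kind,
                   regulation = network$nodes$regulation,
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = vx)
}

#' Read a GraphML network back into a co-expression network
#'
#' Inverse of [write_network()] with `format = "graphml"`.
#'
#' @param path GraphML file written by this package.
#' @return A `coexpression_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(
    id = igraph::vertex_attr(g, "name"),
    kind = igraph::vertex_attr(g, "kind"),
    regulation = igraph::vertex_attr(g, "regulation")
  )
  el <- igraph::as_edgelist(g)
  kind <- setNames(nodes$kind, nodes$id)
  # orient every edge lncRNA -> gene regardless of storage order
  flip <- kind[el[, 1]] == "gene"
  el_l <- if_else(flip, el[, 2], el[, 1])
  el_g <- if_else(flip, el[, 1], el[, 2])
  edges <- tibble(
    lncrna_id = el_l, gene_id = el_g,
    mode = igraph::edge_attr(g, "mode"),
    r = igraph::edge_attr(g, "r"),
    p = igraph::edge_attr(g, "p")
  )
  new_coexpression_network(nodes, edges)
}
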