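#' Build a validated genome annotation
#'
#' The central annotation container: genes, transcripts and exons as tibbles,
#' all on a single internal coordinate convention (0-based, half-open
#' intervals). Transcript spans, exon counts and spliced lengths are derived
#' from the exon table, never trusted from the caller.
#'
#' @param exons Tibble with columns `transcript_id`, `gene_id`, `chromosome`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open) and
#'   optionally `biotype` (one of `"known_mRNA"`, `"novel"`,
#'   `"lncRNA_candidate"`; default `"known_mRNA"`).
#' @param chrom_sizes Optional tibble with columns `chromosome` and `length`
#'   (bp). When given, every exon must lie within its chromosome.
#' @param gene_biotype Optional tibble with columns `gene_id`, `biotype`
#'   overriding the per-gene biotype derived from transcripts.
#'
#' @return An object of class `genome_annotation`: a list with tibbles
#'   `genes`, `transcripts`, `exons` and (possibly `NULL`) `chrom_sizes`.
#' @export
genome_annotation <- function(exons, chrom_sizes = NULL, gene_biotype = NULL) {
  required <- c("transcript_id", "gene_id", "chromosome", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  exons <- as_tibble(exons)
  if (!"biotype" %in% names(exons)) exons$biotype <- "known_mRNA"
  if (nrow(exons) == 0) abort("annotation must contain at least one exon")
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("exon strand must be '+' or '-'")
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end - exons$start < 1L)) {
    abort("every exon must have length >= 1 bp")
  }
  if (any(exons$start < 0L)) abort("exon start before chromosome origin")

  exons <- exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup()

  # exons within a transcript must not overlap (half-open intervals)
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(ok = all(diff(.data$start) > 0) &&
                all(.data$start[-1] >= .data$end[-length(.data$end)]),
              .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("overlapping exons within transcript(s): ",
                 paste(head(bad$transcript_id, 5), collapse = ", ")))
  }

  multi_chrom <- exons %>%
    distinct(.data$transcript_id, .data$chromosome, .data$strand, .data$gene_id) %>%
    dplyr::count(.data$transcript_id) %>%
    filter(.data$n > 1)
  if (nrow(multi_chrom) > 0) {
    abort(paste0("transcript(s) span multiple chromosomes/strands/genes: ",
                 paste(head(multi_chrom$transcript_id, 5), collapse = ", ")))
  }

  transcripts <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chromosome,
             .data$strand, .data$biotype) %>%
    summarise(spliced_length = sum(.data$end - .data$start),
              n_exons = dplyr::n(),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("transcript_id", "gene_id", "chromosome", "strand", "biotype",
           "start", "end", "n_exons", "spliced_length") %>%
    arrange(.data$transcript_id)

  genes <- transcripts %>%
    group_by(.data$gene_id, .data$chromosome, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              biotype = if (all(.data$biotype == "known_mRNA"))
                "protein_coding" else "novel_locus",
              .groups = "drop") %>%
    arrange(.data$gene_id)
  if (!is.null(gene_biotype)) {
    genes <- genes %>%
      left_join(rename(as_tibble(gene_biotype), biotype_new = "biotype"),
                by = "gene_id") %>%
      mutate(biotype = dplyr::coalesce(.data$biotype_new, .data$biotype)) %>%
      select(-"biotype_new")
  }

  if (!is.null(chrom_sizes)) {
    chrom_sizes <- as_tibble(chrom_sizes)
    if (!all(c("chromosome", "length") %in% names(chrom_sizes))) {
      abort("chrom_sizes needs columns 'chromosome' and 'length'")
    }
    chk <- exons %>% left_join(chrom_sizes, by = "chromosome")
    if (any(is.na(chk$length))) {
      abort(paste0("exon chromosome absent from chrom_sizes: ",
                   paste(unique(chk$chromosome[is.na(chk$length)]), collapse = ", ")))
    }
    if (any(chk$end > chk$length)) {
      off <- unique(chk$transcript_id[chk$end > chk$length])
      abort(paste0("exon beyond declared chromosome end in transcript(s): ",
                   paste(head(off, 5), collapse = ", ")))
    }
  }

  structure(
    list(genes = genes, transcripts = transcripts,
         exons = select(exons, "transcript_id", "gene_id", "chromosome",
                        "strand", "start", "end", "exon_rank", "biotype"),
         chrom_sizes = chrom_sizes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exons\n", sep = "")
  bt <- table(x$transcripts$biotype)
  cat("  transcript biotypes:",
      paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$chrom_sizes)) {
    cat("  chromosomes:", nrow(x$chrom_sizes), "with declared sizes\n")
  }
  invisible(x)
}

#' Subset an annotation to a set of transcripts
#'
#' @param annotation A `genome_annotation`.
#' @param transcript_ids Character vector of transcript ids to keep.
#' @return A `genome_annotation` restricted to those transcripts.
#' @export
filter_transcripts <- function(annotation, transcript_ids) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- filter(annotation$exons, .data$transcript_id %in% transcript_ids)
  if (nrow(ex) == 0) abort("no exons left after subsetting")
  genome_annotation(ex, chrom_sizes = annotation$chrom_sizes)
}

# GRanges view of the exon table (internal): converts half-open back to
# 1-based closed for IRanges arithmetic.
exons_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chromosome,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id
  )
}

spans_granges <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$chromosome,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = tbl$strand
  )
}
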