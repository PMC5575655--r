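#' Classify lncRNAs by position relative to a reference annotation
#'
#' Each lncRNA receives exactly one positional class, with precedence
#' antisense > intronic > lincRNA:
#' \itemize{
#'   \item \strong{antisense} — any exon overlaps an exon of a reference gene
#'     on the opposite strand;
#'   \item \strong{intronic} — the transcript lies entirely inside an intron
#'     of a reference gene (either strand by default) with no exonic overlap;
#'   \item \strong{lincRNA} — everything else (intergenic).
#' }
#' A lncRNA on a chromosome absent from the reference is classified lincRNA
#' with a warning. Distance to the nearest reference gene is 0 when spans
#' overlap.
#'
#' @param lncrnas A [genome_annotation()] (or its `transcripts`/`exons`
#'   subset) of confirmed lncRNAs.
#' @param annotation Reference [genome_annotation()].
#' @param intronic_same_strand_only Logical; when `TRUE`, intronic
#'   containment counts only on the host gene's strand.
#' @return Tibble with `transcript_id`, `positional_class`,
#'   `nearest_gene_id`, `distance` (bp, 0 if overlapping).
#' @export
classify_position <- function(lncrnas, annotation,
                              intronic_same_strand_only = FALSE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (inherits(lncrnas, "genome_annotation")) {
    lnc_tx <- lncrnas$transcripts
    lnc_ex <- lncrnas$exons
  } else {
    abort("lncrnas must be a genome_annotation")
  }
  if (nrow(lnc_tx) == 0) abort("no lncRNAs to classify")

  ref_genes <- filter(annotation$genes, .data$biotype == "protein_coding")
  ref_tx_ids <- annotation$transcripts$transcript_id[
    annotation$transcripts$gene_id %in% ref_genes$gene_id]
  ref_ex <- filter(annotation$exons, .data$transcript_id %in% ref_tx_ids)

  off_chrom <- setdiff(unique(lnc_tx$chromosome), unique(ref_genes$chromosome))
  if (length(off_chrom) > 0) {
    warn(paste0("lncRNA chromosome(s) absent from reference annotation: ",
                paste(off_chrom, collapse = ", "),
                "; classifying as lincRNA"))
  }

  lnc_gr <- exons_granges(lnc_ex)
  ref_gr <- exons_granges(ref_ex)

  # antisense: exon-exon overlap on the opposite strand (seqlevel-mismatch
  # warnings are expected when a lncRNA chromosome is absent — handled above)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(lnc_gr, ref_gr, ignore.strand = TRUE))
  opp <- as.character(GenomicRanges::strand(lnc_gr))[S4Vectors::queryHits(hits)] !=
    as.character(GenomicRanges::strand(ref_gr))[S4Vectors::subjectHits(hits)]
  antisense_ids <- unique(
    S4Vectors::mcols(lnc_gr)$transcript_id[S4Vectors::queryHits(hits)[opp]])

  # any exonic overlap at all (same or opposite strand) blocks intronic
  exonic_any <- unique(
    S4Vectors::mcols(lnc_gr)$transcript_id[S4Vectors::queryHits(hits)])

  # introns of reference transcripts
  introns <- ref_ex %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chromosome, .data$strand) %>%
    summarise(int_start = list(.data$end[-dplyr::n()]),
              int_end = list(.data$start[-1]), .groups = "drop") %>%
    tidyr::unnest(c("int_start", "int_end"))
  intronic_ids <- character(0)
  if (nrow(introns) > 0) {
    int_gr <- GenomicRanges::GRanges(
      seqnames = introns$chromosome,
      ranges = IRanges::IRanges(start = introns$int_start + 1L,
                                end = introns$int_end),
      strand = introns$strand
    )
    span_gr <- spans_granges(lnc_tx)
    within_hits <- suppressWarnings(GenomicRanges::findOverlaps(
      span_gr, int_gr, type = "within",
      ignore.strand = !intronic_same_strand_only))
    intronic_ids <- unique(lnc_tx$transcript_id[S4Vectors::queryHits(within_hits)])
  }

  gene_gr <- spans_granges(ref_genes)
  span_gr <- spans_granges(lnc_tx)
  nearest <- suppressWarnings(
    GenomicRanges::distanceToNearest(span_gr, gene_gr, ignore.strand = TRUE))
  nearest_gene <- rep(NA_character_, nrow(lnc_tx))
  distance <- rep(NA_real_, nrow(lnc_tx))
  nearest_gene[S4Vectors::queryHits(nearest)] <-
    ref_genes$gene_id[S4Vectors::subjectHits(nearest)]
  distance[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance

  tibble(
    transcript_id = lnc_tx$transcript_id,
    positional_class = case_when(
      lnc_tx$transcript_id %in% antisense_ids ~ "antisense",
      lnc_tx$transcript_id %in% intronic_ids &
        !(lnc_tx$transcript_id %in% exonic_any) ~ "intronic",
      TRUE ~ "lincRNA"
    ),
    nearest_gene_id = nearest_gene,
    distance = distance
  )
}

#' Per-class counts and percentages
#'
#' Percentages are `count / total * 100`, reported to one decimal; the
#' rounding residue (deviation of the percentage sum from 100) is attached as
#' attribute `rounding_residue`.
#'
#' @param classified Tibble with a `positional_class` column (or any
#'   character vector of class labels).
#' @return Tibble with `positional_class`, `n`, `percent`.
#' @export
class_proportions <- function(classified) {
  labels <- if (is.data.frame(classified)) classified$positional_class
            else as.character(classified)
  if (length(labels) == 0) abort("cannot compute proportions of an empty set")
  out <- tibble(positional_class = labels) %>%
    dplyr::count(.data$positional_class, name = "n") %>%
    mutate(percent = round(.data$n / sum(.data$n) * 100, 1)) %>%
    arrange(dplyr::desc(.data$n))
  attr(out, "rounding_residue") <- sum(out$percent) - 100
  out
}

#' Feature and genome-size share per chromosome
#'
#' @param features Tibble with a `chromosome` column (one row per feature).
#' @param chrom_sizes Tibble with `chromosome`, `length` covering all
#'   feature chromosomes.
#' @return Tibble with `chromosome`, `n_features`, `feature_share`,
#'   `size_share`; both share columns sum to 1.
#' @export
chromosome_distribution <- function(features, chrom_sizes) {
  chrom_sizes <- as_tibble(chrom_sizes)
  missing_c <- setdiff(unique(features$chromosome), chrom_sizes$chromosome)
  if (length(missing_c) > 0) {
    abort(paste0("chromosome(s) without declared size: ",
                 paste(missing_c, collapse = ", ")))
  }
  counts <- features %>% dplyr::count(.data$chromosome, name = "n_features")
  chrom_sizes %>%
    left_join(counts, by = "chromosome") %>%
    mutate(n_features = dplyr::coalesce(.data$n_features, 0L),
           feature_share = .data$n_features / sum(.data$n_features),
           size_share = .data$length / sum(.data$length)) %>%
    select("chromosome", "n_features", "feature_share", "size_share")
}

#' Exon-count and exon-size summaries
#'
#' @param annotation A [genome_annotation()] (summaries run over all its
#'   transcripts).
#' @param size_breaks Bin edges (bp) for the exon-size histogram; the last
#'   bin is open-ended.
#' @return List with `mean_exons`, tibble `exon_count_hist`
#'   (`n_exons`, `n_transcripts`) and tibble `exon_size_hist` (`bin`,
#'   left-closed `[lo, hi)` labels, `n_exons`).
#' @export
exon_statistics <- function(annotation,
                            size_breaks = c(seq(0, 1000, by = 100), Inf)) {
  stopifnot(inherits(annotation, "genome_annotation"))
  tx <- annotation$transcripts
  if (nrow(tx) == 0) abort("no transcripts")
  ex_len <- annotation$exons$end - annotation$exons$start
  count_hist <- tx %>% dplyr::count(.data$n_exons, name = "n_transcripts")
  cuts <- cut(ex_len, breaks = size_breaks, right = FALSE,
              include.lowest = FALSE)
  size_hist <- tibble(bin = levels(cuts)) %>%
    left_join(tibble(bin = as.character(cuts)) %>%
                dplyr::count(.data$bin, name = "n_exons"),
              by = "bin") %>%
    mutate(n_exons = dplyr::coalesce(.data$n_exons, 0L))
  list(
    mean_exons = sum(tx$n_exons) / nrow(tx),
    exon_count_hist = count_hist,
    exon_size_hist = size_hist
  )
}

#' Percentage of a total, rounded for reporting
#'
#' Tiny reporting helper used for read-mapping strand summaries and class
#' percentage tables.
#'
#' @param x Numerator(s).
#' @param total Denominator(s).
#' @param digits Decimal places to round to.
#' @return Numeric percentage(s).
#' @export
percentage <- function(x, total, digits = 2) {
  if (any(total <= 0)) abort("total must be positive")
  round(x / total * 100, digits)
}
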