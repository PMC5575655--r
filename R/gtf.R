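#' Read a GTF file into a genome annotation
#'
#' GTF coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention at this boundary; all downstream interval arithmetic
#' uses the internal convention only.
#'
#' For the `"assembled"` dialect, novelty is taken from a `class_code`
#' attribute when present (`"="` marks a known transcript, anything else is
#' novel, matching assembler comparison codes); otherwise, when a `reference`
#' annotation is supplied, transcripts absent from it are novel; otherwise all
#' transcripts are treated as novel.
#'
#' @param path Path to a GTF file.
#' @param dialect `"reference"` (known gene models) or `"assembled"`
#'   (assembler output possibly mixing known and novel transcripts).
#' @param chrom_sizes Optional chromosome-size tibble (`chromosome`,
#'   `length`); exons beyond a declared size raise a validation error.
#' @param reference Optional `genome_annotation` used to call novelty by
#'   absence when the assembled GTF has no `class_code` attribute.
#'
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path, dialect = c("reference", "assembled"),
                     chrom_sizes = NULL, reference = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  validate_gtf_lines(path)

  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) abort(paste0("no exon records in GTF: ", path))
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id) ||
      anyNA(mc$gene_id) || anyNA(mc$transcript_id)) {
    abort("GTF exon records must carry gene_id and transcript_id attributes")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) abort("GTF exon records must be stranded")

  exons <- tibble(
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)
  )

  if (dialect == "reference") {
    exons$biotype <- "known_mRNA"
  } else {
    if (!is.null(mc$class_code)) {
      code <- as.character(mc$class_code)
      exons$biotype <- if_else(!is.na(code) & code == "=", "known_mRNA", "novel")
    } else if (!is.null(reference)) {
      known <- reference$transcripts$transcript_id
      exons$biotype <- if_else(exons$transcript_id %in% known,
                               "known_mRNA", "novel")
    } else {
      exons$biotype <- "novel"
    }
  }
  genome_annotation(exons, chrom_sizes = chrom_sizes)
}

# Cheap structural pre-validation so parse failures name the offending line.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(body)
  if (length(idx) == 0) abort(paste0("GTF has no feature lines: ", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9)
  if (length(bad) > 0) {
    abort(paste0("malformed GTF line ", idx[bad[1]], " in ", path,
                 ": expected >= 9 tab-separated fields, got ", nf[bad[1]]))
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad) > 0) {
    abort(paste0("malformed GTF line ", idx[bad[1]], " in ", path,
                 ": non-numeric start/end"))
  }
  invisible(TRUE)
}

#' Write a genome annotation as GTF
#'
#' Exon records only, converted back from the internal 0-based half-open
#' convention to GTF's 1-based closed intervals. Transcript biotype and (for
#' assembled-style output) a `class_code` attribute are persisted so
#' [read_gtf()] round-trips the annotation.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @param class_code Logical; write a `class_code` attribute (`"="` for
#'   `known_mRNA` transcripts, `"u"` otherwise) as assemblers do.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, class_code = FALSE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chromosome,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  mc <- S4Vectors::DataFrame(
    type = "exon",
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    exon_number = as.character(ex$exon_rank)
  )
  if (class_code) {
    mc$class_code <- if_else(ex$biotype == "known_mRNA", "=", "u")
  }
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gtf")
  # drop the date-stamped header comments so identical annotations yield
  # byte-identical files
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "##date") & !startsWith(lines, "##source-version")
  writeLines(lines[keep], path)
  invisible(path)
}
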