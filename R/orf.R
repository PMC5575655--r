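#' Find the longest open reading frame on the sense strand
#'
#' Scans all three reading frames for the longest ATG-to-stop ORF. The
#' reported length includes the stop codon. Codons containing `N` are never
#' starts or stops (they may sit inside an ORF). Coordinates are 0-based
#' half-open nucleotide offsets into the input sequence.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return A list with `start`, `end`, `length` (nt) and `frame` (0, 1, 2).
#'   `length` is 0 (and the rest `NA`) when no ORF exists.
#' @export
find_longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- toupper(sequence)
  n <- nchar(s)
  best <- list(start = NA_integer_, end = NA_integer_,
               length = 0L, frame = NA_integer_)
  if (n < 6) return(best)
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    starts_nt <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(starts_nt) < 2) next
    codons <- substring(s, starts_nt, starts_nt + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (length(atg) == 0 || length(stp) == 0) next
    # first stop at or after each ATG (an ATG cannot itself be a stop)
    pos <- findInterval(atg - 0.5, stp) + 1L
    ok <- pos <= length(stp)
    if (!any(ok)) next
    len_codons <- stp[pos[ok]] - atg[ok] + 1L
    i <- which.max(len_codons)
    len_nt <- len_codons[i] * 3L
    if (len_nt > best$length) {
      start0 <- starts_nt[atg[ok][i]] - 1L
      best <- list(start = start0, end = start0 + len_nt,
                   length = len_nt, frame = f)
    }
  }
  best
}

#' Longest-ORF length for many sequences
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return Integer vector of longest-ORF lengths (nt), same names.
#' @export
orf_lengths <- function(sequences) {
  vapply(sequences, function(s) find_longest_orf(s)$length, integer(1))
}
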