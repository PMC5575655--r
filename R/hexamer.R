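#' Build an in-frame hexamer frequency table
#'
#' Counts hexamers at step 3 (frame 0) across a set of sequences and returns
#' pseudocounted relative frequencies over all 4096 hexamers. Used to train
#' the coding and noncoding background models for [hexamer_ratio()].
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param pseudocount Added to every hexamer count before normalising.
#' @return Named numeric vector of length 4096 summing to 1.
#' @export
build_hexamer_table <- function(sequences, pseudocount = 1) {
  stopifnot(length(sequences) > 0, pseudocount > 0)
  all_hex <- all_hexamers()
  counts <- setNames(numeric(4096), all_hex)
  for (s in toupper(sequences)) {
    n <- nchar(s)
    if (n < 6) next
    starts <- seq.int(1L, n - 5L, by = 3L)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[hx %in% all_hex]  # drops N-containing hexamers
    if (length(hx) == 0) next
    tb <- table(hx)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts <- counts + pseudocount
  counts / sum(counts)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  do.call(paste0, expand.grid(b, b, b, b, b, b,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)[, 6:1])
}

#' Hexamer usage log-likelihood ratio
#'
#' Mean over the in-frame hexamers (step 3, frame 0) of
#' `log(coding_freq / noncoding_freq)`. Positive values suggest coding
#' sequence. Hexamers containing `N` are skipped; a sequence with no scorable
#' hexamer returns 0.
#'
#' @param sequence A single nucleotide string.
#' @param coding_freqs,noncoding_freqs Named frequency vectors over all 4096
#'   hexamers (see [build_hexamer_table()]).
#' @return A single numeric log-ratio.
#' @export
hexamer_ratio <- function(sequence, coding_freqs, noncoding_freqs) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (length(coding_freqs) == 0 || length(noncoding_freqs) == 0) {
    abort("hexamer frequency tables must be non-empty")
  }
  if (any(coding_freqs <= 0) || any(noncoding_freqs <= 0)) {
    abort("hexamer frequency tables must be strictly positive (pseudocounted)")
  }
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6) return(0)
  starts <- seq.int(1L, n - 5L, by = 3L)
  hx <- substring(s, starts, starts + 5L)
  hx <- hx[hx %in% names(coding_freqs) & hx %in% names(noncoding_freqs)]
  if (length(hx) == 0) return(0)
  mean(log(unname(coding_freqs[hx]) / unname(noncoding_freqs[hx])))
}
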