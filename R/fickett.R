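# Fickett TESTCODE lookup tables. For each base there are ten probability
# buckets for the position parameter (max/(min+1) of the three codon-position
# counts) and ten for the composition parameter (base fraction), selected by
# the first threshold the parameter value reaches, plus a per-base weight.
fickett_tables <- list(
  position = list(
    thresholds = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
    prob = list(
      A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
      C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
      G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
      T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
    ),
    weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  ),
  content = list(
    thresholds = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0),
    prob = list(
      A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
      C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
      G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
      T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
    ),
    weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  )
)

fickett_lookup <- function(value, thresholds, probs) {
  idx <- which(value >= thresholds)[1]
  probs[idx]
}

#' Fickett TESTCODE score
#'
#' The classic position/composition statistic separating coding from
#' noncoding nucleotide sequences. For each base, a position parameter
#' (asymmetry of the base's usage across the three codon positions,
#' `max/(min+1)`) and a composition parameter (base fraction) are mapped
#' through the published lookup tables and combined as a weighted sum.
#' Higher scores indicate coding-like sequence. The score is strand-specific:
#' the reverse complement of a sequence generally scores differently.
#'
#' @param sequence A single nucleotide string (case-insensitive); `N`s are
#'   ignored in the composition counts and never counted in position usage.
#' @return A single numeric score.
#' @export
fickett_score <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6) abort("fickett_score needs a sequence of at least 2 codons")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  pos_index <- rep_len(1:3, n)
  score <- 0
  total_acgt <- sum(chars %in% bases)
  if (total_acgt == 0) abort("sequence contains no A/C/G/T characters")
  for (b in bases) {
    hit <- chars == b
    counts <- vapply(1:3, function(k) sum(hit & pos_index == k), numeric(1))
    pos_param <- max(counts) / (min(counts) + 1)
    content <- sum(hit) / total_acgt
    score <- score +
      fickett_lookup(pos_param, fickett_tables$position$thresholds,
                     fickett_tables$position$prob[[b]]) *
        fickett_tables$position$weight[[b]] +
      fickett_lookup(content, fickett_tables$content$thresholds,
                     fickett_tables$content$prob[[b]]) *
        fickett_tables$content$weight[[b]]
  }
  unname(score)
}
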