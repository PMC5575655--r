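#' Compute coding-potential features for a set of sequences
#'
#' The four features behind the trained coding/noncoding classifiers:
#' longest-ORF length, ORF coverage (ORF length over transcript length),
#' Fickett TESTCODE score and the hexamer usage log-ratio.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param coding_hexamers,noncoding_hexamers Hexamer frequency tables from
#'   [build_hexamer_table()].
#' @return Tibble with columns `transcript_id`, `orf_length`, `orf_coverage`,
#'   `fickett`, `hexamer`.
#' @export
coding_features <- function(sequences, coding_hexamers, noncoding_hexamers) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  tibble(
    transcript_id = names(sequences),
    orf_length = orf_lengths(sequences),
    orf_coverage = orf_lengths(sequences) / nchar(sequences),
    fickett = vapply(sequences, fickett_score, numeric(1)),
    hexamer = vapply(sequences, hexamer_ratio, numeric(1),
                     coding_freqs = coding_hexamers,
                     noncoding_freqs = noncoding_hexamers)
  )
}

#' Train a logistic coding/noncoding classifier
#'
#' Fits a logistic regression of the coding label on a subset of the
#' coding-potential features. Two configurations are used by the discovery
#' funnel: the full four-feature model and a Fickett+hexamer model.
#'
#' @param features Tibble from [coding_features()] (or with the same
#'   columns).
#' @param labels Character or factor vector, one of `"coding"`,
#'   `"noncoding"` per row of `features`.
#' @param feature_names Which feature columns to use.
#' @param threshold Probability above which a sequence is voted coding.
#' @return An object of class `coding_classifier`.
#' @export
train_coding_classifier <- function(features,
                                    labels,
                                    feature_names = c("orf_length",
                                                      "orf_coverage",
                                                      "fickett", "hexamer"),
                                    threshold = 0.5) {
  stopifnot(nrow(features) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("coding", "noncoding"))) {
    abort("labels must be 'coding' or 'noncoding'")
  }
  if (length(unique(labels)) < 2) {
    abort("training data must contain both classes")
  }
  n_min <- min(table(labels))
  if (n_min < 20) {
    warn(paste0("fewer than 20 training sequences in the smaller class (",
                n_min, "); coefficients may be unstable"))
  }
  dat <- as.data.frame(features[, feature_names, drop = FALSE])
  dat$.y <- as.integer(labels == "coding")
  # separable synthetic classes legitimately drive fitted probabilities to
  # 0/1; the glm warning adds nothing here
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial())
  )
  prob <- unname(predict(fit, type = "response"))
  acc <- mean((prob > threshold) == (dat$.y == 1))
  structure(
    list(fit = fit, feature_names = feature_names, threshold = threshold,
         training_accuracy = acc, n_train = nrow(dat)),
    class = "coding_classifier"
  )
}

#' @export
print.coding_classifier <- function(x, ...) {
  cat("<coding_classifier> logistic model on ",
      paste(x$feature_names, collapse = ", "), "\n",
      "  n = ", x$n_train, ", training accuracy = ",
      round(x$training_accuracy, 3), ", vote threshold = ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Predict coding probability and vote
#'
#' @param object A `coding_classifier`.
#' @param newdata Tibble with the classifier's feature columns.
#' @param ... Unused.
#' @return Tibble with `prob_coding` and `vote` (`"coding"`/`"noncoding"`).
#' @export
predict.coding_classifier <- function(object, newdata, ...) {
  dat <- as.data.frame(newdata[, object$feature_names, drop = FALSE])
  prob <- unname(predict(object$fit, newdata = dat, type = "response"))
  tibble(prob_coding = prob,
         vote = if_else(prob > object$threshold, "coding", "noncoding"))
}

#' @rdname train_coding_classifier
#' @param x A `coding_classifier`.
#' @param ... Unused.
#' @export
tidy.coding_classifier <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std_error = co[, 2],
         statistic = co[, 3], p_value = co[, 4])
}

#' @rdname train_coding_classifier
#' @export
glance.coding_classifier <- function(x, ...) {
  tibble(n_train = x$n_train, training_accuracy = x$training_accuracy,
         threshold = x$threshold, deviance = x$fit$deviance,
         null_deviance = x$fit$null.deviance, aic = x$fit$aic)
}

#' Mononucleotide-shuffle sequences
#'
#' Permutes the letters of each sequence, preserving base composition while
#' destroying codon structure and ORFs. Used to build a noncoding training
#' class from known mRNAs when no curated noncoding set exists.
#'
#' @param sequences Character vector.
#' @return Character vector of shuffled sequences, same names.
#' @export
shuffle_sequences <- function(sequences) {
  vapply(sequences, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1))
}
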