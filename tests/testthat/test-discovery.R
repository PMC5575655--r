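test_that("structural filter applies the 200 nt / 2 exon floors inclusively", {
  tx <- tibble::tibble(
    transcript_id = c("short2ex", "long1ex", "exact200", "both_bad"),
    spliced_length = c(150, 500, 200, 150),
    n_exons = c(2, 1, 2, 1)
  )
  out <- structural_filter(tx)
  expect_equal(out$structural_pass,
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$structural_reason[1], "too_short")
  expect_equal(out$structural_reason[2], "single_exon")
  expect_true(is.na(out$structural_reason[3]))
  expect_equal(out$structural_reason[4], "too_short;single_exon")
})

test_that("find_longest_orf handles hand-checkable cases", {
  o <- find_longest_orf("ATGAAATAG")
  expect_equal(o$length, 9L)
  expect_equal(o$frame, 0L)
  expect_equal(o$start, 0L)
  expect_equal(o$end, 9L)
  expect_equal(find_longest_orf("CCCCCC")$length, 0L)
  # N never starts or stops an ORF
  expect_equal(find_longest_orf("NTGAAATAG")$length, 0L)
  # frame-1 ORF
  expect_equal(find_longest_orf("CATGAAATAGC")$frame, 1L)
})

test_that("find_longest_orf matches the brute-force oracle on random sequence", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_seq(sample(50:600, 1))
    expect_equal(find_longest_orf(s)$length, orf_oracle(s), info = s)
  }
})

test_that("fickett_score agrees with a straight-from-table reimplementation", {
  # independent lookup written directly against the published tables
  oracle <- function(seq) {
    s <- strsplit(toupper(seq), "")[[1]]
    tabs <- lncfunnel:::fickett_tables
    total <- 0
    for (b in c("A", "C", "G", "T")) {
      cnt <- c(sum(s[seq(1, length(s), 3)] == b),
               sum(s[seq(2, length(s), 3)] == b),
               sum(s[seq(3, length(s), 3)] == b))
      posv <- max(cnt) / (min(cnt) + 1)
      comp <- sum(s == b) / sum(s %in% c("A", "C", "G", "T"))
      pp <- tabs$position$prob[[b]][which(posv >= tabs$position$thresholds)[1]]
      cp <- tabs$content$prob[[b]][which(comp >= tabs$content$thresholds)[1]]
      total <- total + pp * tabs$position$weight[[b]] +
        cp * tabs$content$weight[[b]]
    }
    total
  }
  seqs <- c(strrep("A", 300), random_seq(300), random_seq(601),
            strrep("ACG", 100))
  for (s in seqs) expect_equal(fickett_score(s), oracle(s))
})

test_that("fickett_score is case-insensitive and strand-specific", {
  s <- random_seq(300)
  expect_equal(fickett_score(tolower(s)), fickett_score(s))
  expect_false(isTRUE(all.equal(fickett_score(reverse_complement(s)),
                                fickett_score(s))))
  expect_error(fickett_score("ACG"), "2 codons")
})

test_that("hexamer_ratio follows its defining arithmetic", {
  uniform <- setNames(rep(1 / 4096, 4096), lncfunnel:::all_hexamers())
  s <- random_seq(120)
  expect_equal(hexamer_ratio(s, uniform, uniform), 0)

  # hand-computed toy: double the frequency of the observed hexamers
  seq12 <- "AAAAAACCCCCC"  # in-frame hexamers: AAAAAA, AAACCC, CCCCCC
  boosted <- uniform
  boosted[c("AAAAAA", "AAACCC", "CCCCCC")] <- 2 / 4096
  boosted <- boosted / sum(boosted)
  expected <- mean(log(boosted[c("AAAAAA", "AAACCC", "CCCCCC")] / 4096^-1))
  expect_equal(hexamer_ratio(seq12, boosted, uniform), unname(expected))
  # sign is forced when every observed hexamer favours coding
  expect_gt(hexamer_ratio(seq12, boosted, uniform), 0)
  expect_error(hexamer_ratio(s, numeric(0), uniform), "non-empty")
})

test_that("the coding classifier separates designed classes and not noise", {
  fix <- default_fixture()
  cls <- fix$truth$classes
  coding_ids <- cls$transcript_id[cls$true_class == "mRNA"]
  lnc_ids <- cls$transcript_id[cls$true_class == "lincRNA"]
  cod_tab <- build_hexamer_table(fix$sequences[coding_ids])
  non_tab <- build_hexamer_table(fix$sequences[lnc_ids])
  feats <- coding_features(fix$sequences[c(coding_ids, lnc_ids)],
                           cod_tab, non_tab)
  labels <- rep(c("coding", "noncoding"),
                c(length(coding_ids), length(lnc_ids)))

  # held-out accuracy on the designed contrast
  set.seed(9)
  test_idx <- sample(seq_along(labels), 40)
  fit <- train_coding_classifier(feats[-test_idx, ], labels[-test_idx])
  pred <- predict(fit, feats[test_idx, ])
  expect_gte(mean((pred$vote == "coding") ==
                    (labels[test_idx] == "coding")), 0.9)
  expect_equal(fit$training_accuracy, 1.0)

  # broom-style accessors
  expect_true(all(c("term", "estimate") %in% names(tidy(fit))))
  expect_equal(glance(fit)$n_train, length(labels) - 40)

  # permuted labels carry no signal: held-out accuracy near chance on a
  # class-balanced subset (imbalance would let the majority class win)
  set.seed(10)
  bal <- c(sample(which(labels == "coding"), 30),
           which(labels == "noncoding"))
  accs <- vapply(1:10, function(k) {
    perm <- sample(labels[bal])
    idx <- sample(seq_along(bal), 20)
    f <- suppressWarnings(train_coding_classifier(feats[bal, ][-idx, ],
                                                  perm[-idx]))
    mean((predict(f, feats[bal, ][idx, ])$vote == "coding") ==
           (perm[idx] == "coding"))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)

  expect_error(train_coding_classifier(feats, rep("coding", nrow(feats))),
               "both classes")
})

test_that("consensus requires unanimity of the enabled methods", {
  votes <- tibble::tibble(
    vote_orf = c("noncoding", "coding", "noncoding"),
    vote_cpat = c("noncoding", "noncoding", "noncoding"),
    vote_cnci = c("noncoding", "noncoding", "coding")
  )
  expect_equal(consensus_noncoding(votes), c(TRUE, FALSE, FALSE))
  expect_equal(consensus_noncoding(votes, c("vote_orf", "vote_cpat")),
               c(TRUE, FALSE, TRUE))
  expect_error(consensus_noncoding(votes, character(0)), "at least one")
})

test_that("the expression floor is a strict inequality", {
  vals <- matrix(c(0.05, 0.1, 0.2), nrow = 3, ncol = 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  out <- expression_floor_filter(c("a", "b", "c"), vals, floor = 0.1)
  expect_equal(out$expression_pass, c(FALSE, FALSE, TRUE))
  expect_error(expression_floor_filter("zz", vals), "zz")
})

test_that("the discovery funnel never adds transcripts and recovers the truth", {
  fix <- default_fixture()
  disc <- default_discovery()
  funnel <- discovery_funnel(disc)
  expect_true(all(diff(funnel$n) <= 0))

  cls <- fix$truth$classes
  lnc_true <- cls$transcript_id[cls$true_class %in%
                                  c("lincRNA", "intronic", "antisense")]
  called <- disc$transcript_id[disc$passed]
  sens <- mean(lnc_true %in% called)
  decoys <- cls$transcript_id[cls$true_class == "decoy_coding"]
  fd <- sum(called %in% decoys) / max(1, length(called))
  expect_gte(sens, 0.9)
  expect_lte(fd, 0.1)
  # junk never survives
  junk <- cls$transcript_id[cls$true_class == "junk"]
  expect_equal(sum(called %in% junk), 0L)
})
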