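test_that("ground truth conserves every planted transcript exactly once", {
  fix <- default_fixture()
  cfg <- fix$config
  classes <- fix$truth$classes
  expect_equal(nrow(classes), nrow(fix$annotation$transcripts))
  expect_equal(anyDuplicated(classes$transcript_id), 0L)
  counts <- table(classes$true_class)
  expect_equal(unname(counts[["lincRNA"]]), cfg$n_linc)
  expect_equal(unname(counts[["intronic"]]), cfg$n_intronic)
  expect_equal(unname(counts[["antisense"]]), cfg$n_antisense)
  expect_equal(unname(counts[["decoy_coding"]]), cfg$n_decoy_coding)
  expect_equal(unname(counts[["junk"]]), cfg$n_junk)
  expect_equal(unname(counts[["mRNA"]]), cfg$n_coding_genes)
})

test_that("every junk transcript violates at least one structural filter", {
  fix <- default_fixture()
  junk <- fix$truth$classes$transcript_id[fix$truth$classes$true_class == "junk"]
  tx <- dplyr::filter(fix$annotation$transcripts, transcript_id %in% junk)
  expect_true(all(tx$spliced_length < 200 | tx$n_exons < 2))
})

test_that("planted cis pairs sit inside the cis window without overlap", {
  fix <- default_fixture()
  cis <- dplyr::filter(fix$truth$pairs, mode == "cis")
  found <- cis_targets(fix$annotation, fix$reference, window = 100000)
  key <- paste(found$lncrna_id, found$gene_id)
  expect_true(all(paste(cis$lncrna_id, cis$gene_id) %in% key))
})

test_that("identical config and seed give byte-identical files", {
  cfg <- synthetic_config(seed = 7, n_chromosomes = 1,
                          chromosome_length = 900000, n_coding_genes = 25,
                          n_linc = 6, n_intronic = 2, n_antisense = 2,
                          n_decoy_coding = 3, n_junk = 3,
                          n_cis_pairs = 2, n_trans_pairs = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
})

test_that("spliced sequence extraction honours exon order and strand", {
  genome <- c(chr1 = "ACGTAACCGGTTACGT")
  ex_plus <- toy_exon_row("p", "gp", "chr1", "+", 0, 6)
  ann <- genome_annotation(ex_plus, gene_biotype = NULL)
  expect_equal(unname(generate_transcript_sequences(genome, ann)), "ACGTAA")

  ex_minus <- toy_exon_row("m", "gm", "chr1", "-", 0, 6)
  ann <- genome_annotation(ex_minus)
  expect_equal(unname(generate_transcript_sequences(genome, ann)), "TTACGT")

  ex_two <- toy_exon_row("d", "gd", "chr1", "+", c(0, 10), c(4, 14))
  ann <- genome_annotation(ex_two)
  s <- generate_transcript_sequences(genome, ann)
  expect_equal(nchar(s[["d"]]), 8L)
  expect_equal(unname(s), "ACGTTTAC")

  ex_far <- toy_exon_row("f", "gf", "chr1", "+", 10, 40)
  expect_error(
    generate_transcript_sequences(genome, genome_annotation(ex_far)),
    "beyond chromosome end"
  )
})

test_that("designed coding transcripts carry long ORFs, planted lncRNAs do not", {
  fix <- default_fixture()
  cls <- fix$truth$classes
  orf <- orf_lengths(fix$sequences)
  coding <- cls$transcript_id[cls$true_class %in% c("mRNA", "decoy_coding")]
  noncoding <- cls$transcript_id[cls$true_class %in%
                                   c("lincRNA", "intronic", "antisense")]
  expect_true(all(orf[coding] >= 300))
  expect_gt(mean(orf[noncoding] < 300), 0.9)
})

test_that("the zero-dispersion limit returns exact means", {
  cfg <- synthetic_config(seed = 3, nb_dispersion = 0,
                          library_size_factor_sd = 0)
  truth <- synthetic_null_truth(cfg, n_features = 10, base_mean = 50,
                                base_sd = 0)
  cm <- simulate_counts(cfg, truth)
  expect_true(all(cm$counts == 50L))
})

test_that("realised pair correlations match the planted target", {
  cfg <- synthetic_config(seed = 11)
  truth <- synthetic_pair_truth(cfg, n_pairs = 100)
  cm <- simulate_counts(cfg, truth)
  lens <- setNames(rep(1000, nrow(cm$counts)), rownames(cm$counts))
  lv <- log10(compute_fpkm(cm, lens)$values + 1)
  rs <- vapply(seq_len(100), function(i) {
    cor(lv[sprintf("PLNC%04d", i), ], lv[sprintf("PGENE%04d", i), ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - cfg$planted_pair_correlation), 0.1)
})

test_that("realised fold changes converge to the planted log2 fold change", {
  cfg <- synthetic_config(seed = 5, nb_dispersion = 0.01)
  truth <- synthetic_pair_truth(cfg, n_pairs = 50)
  cm <- simulate_counts(cfg, truth)
  mu_f <- rowMeans(cm$counts[, 1:3])
  mu_a <- rowMeans(cm$counts[, 7:9])
  realised <- abs(log2((mu_a + 0.01) / (mu_f + 0.01)))
  # planted |log2FC| between fetus and adult is 2 * planted_log2fc
  expect_lt(abs(mean(realised) - 2 * cfg$planted_log2fc), 0.3)
})

test_that("lncRNAs are expressed below mRNAs on average", {
  fix <- default_fixture()
  fp <- default_fpkm()
  cls <- fix$truth$classes
  lnc <- cls$transcript_id[cls$true_class %in%
                             c("lincRNA", "intronic", "antisense")]
  mrna <- cls$transcript_id[cls$true_class == "mRNA"]
  # compared on the log scale, as FPKM distributions are drawn
  expect_lt(mean(log10(fp$values[lnc, ] + 1)),
            mean(log10(fp$values[mrna, ] + 1)))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(planted_pair_correlation = 1), "-1, 1")
  expect_error(synthetic_config(nb_dispersion = -1), ">= 0")
  expect_error(synthetic_config(n_linc = 5, n_cis_pairs = 4,
                                n_trans_pairs = 4), "pairs")
})
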