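test_that("cis targets respect the window and the no-overlap rule", {
  ref <- genome_annotation(dplyr::bind_rows(
    toy_exon_row("t_near", "g_near", "chr1", "+", c(50000, 58000),
                 c(51000, 60000)),
    toy_exon_row("t_far", "g_far", "chr1", "+", c(200000, 208000),
                 c(201000, 210000)),
    toy_exon_row("t_ovl", "g_ovl", "chr1", "+", c(10500, 11500),
                 c(10800, 12000))
  ))
  lnc <- tibble::tibble(transcript_id = "lnc1", chromosome = "chr1",
                        start = 10000, end = 11000)
  hits <- cis_targets(lnc, ref, window = 100000)
  expect_equal(hits$gene_id, "g_near")
  expect_equal(hits$distance, 39000)
  # enlarging the window never removes a pair
  wider <- cis_targets(lnc, ref, window = 500000)
  expect_true(all(paste(hits$lncrna_id, hits$gene_id) %in%
                    paste(wider$lncrna_id, wider$gene_id)))
  expect_true("g_far" %in% wider$gene_id)
  expect_false("g_ovl" %in% wider$gene_id)
})

test_that("complementarity scoring is exact, symmetric and discriminative", {
  set.seed(21)
  lnc <- random_seq(400)
  expect_equal(complementarity_score(lnc, reverse_complement(lnc)), 1)

  # brute-force oracle on short equal-length toys, plus windowing symmetry
  brute <- function(a, b, w) {
    rc <- reverse_complement(b)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(rc, "")[[1]]
    best <- 0
    for (s in (-(length(av) - w)):(length(bv) - w)) {
      i <- max(1, 1 - s):min(length(av), length(bv) - s)
      m <- av[i] == bv[i + s]
      if (length(m) < w) next
      runs <- vapply(seq_len(length(m) - w + 1),
                     function(k) sum(m[k:(k + w - 1)]), numeric(1))
      best <- max(best, max(runs) / w)
    }
    best
  }
  for (i in 1:5) {
    a <- random_seq(60); b <- random_seq(60)
    expect_equal(complementarity_score(a, b, window = 20),
                 brute(a, b, 20))
    expect_equal(complementarity_score(a, b, window = 20),
                 complementarity_score(b, a, window = 20))
  }

  # unrelated sequences never reach the 0.9 threshold
  scores <- vapply(1:100, function(i)
    complementarity_score(random_seq(300), random_seq(300)), numeric(1))
  expect_lt(max(scores), 0.9)
  expect_error(complementarity_score("", "ACGT"), "empty")
})

test_that("trans targets recover the planted complementary pairs", {
  fix <- default_fixture()
  truth <- fix$truth
  tp <- dplyr::filter(truth$pairs, mode == "trans")
  mrna_of_gene <- setNames(
    truth$classes$transcript_id[truth$classes$true_class == "mRNA"],
    truth$classes$gene_id[truth$classes$true_class == "mRNA"])
  lnc_seqs <- fix$sequences[tp$lncrna_id]
  gene_seqs <- setNames(fix$sequences[mrna_of_gene[tp$gene_id]], tp$gene_id)
  hits <- trans_targets(lnc_seqs, gene_seqs)
  expect_true(all(paste(tp$lncrna_id, tp$gene_id) %in%
                    paste(hits$lncrna_id, hits$gene_id)))
  expect_true(all(hits$score[match(paste(tp$lncrna_id, tp$gene_id),
                                   paste(hits$lncrna_id, hits$gene_id))] == 1))
})

test_that("the co-expression screen applies signed r and the p cut", {
  samples <- tibble::tibble(
    sample = paste0("s", 1:9),
    stage = rep(c("fetus", "lamb", "adult"), each = 3),
    replicate = rep(1:3, 3)
  )
  # profiles engineered to be exactly (anti-)linear after the log10(x + 1)
  # transform the screen applies
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  lv <- rbind(lnc1 = base, lnc2 = base)
  gv <- rbind(gpos = (base + 1)^2 - 1, gneg = 100 / (base + 1) - 1)
  colnames(lv) <- colnames(gv) <- samples$sample
  lf <- fpkm_matrix(lv, samples, "lncRNA")
  gf <- fpkm_matrix(gv, samples, "gene")
  pairs <- tibble::tibble(lncrna_id = c("lnc1", "lnc2"),
                          gene_id = c("gpos", "gneg"),
                          mode = c("cis", "trans"))
  out <- coexpression_screen(pairs, lf, gf)
  expect_equal(out$r[1], 1)
  expect_true(out$passes[1])
  expect_equal(out$r[2], -1)
  expect_false(out$passes[2])
  # absolute-value mode admits the negative pair
  out_abs <- coexpression_screen(pairs, lf, gf, use_abs = TRUE)
  expect_true(all(out_abs$passes))

  # r and p match the direct formula on a 9-sample toy
  set.seed(22)
  x <- rexp(9, 1 / 10); y <- x + rnorm(9, 0, 2)
  lf2 <- fpkm_matrix(rbind(l = x), samples, "lncRNA")
  gf2 <- fpkm_matrix(rbind(g = y), samples, "gene")
  o2 <- coexpression_screen(tibble::tibble(lncrna_id = "l", gene_id = "g",
                                           mode = "cis"), lf2, gf2)
  r_hand <- cor(log10(x + 1), log10(y + 1))
  t_hand <- r_hand * sqrt(7) / sqrt(1 - r_hand^2)
  expect_equal(o2$r, r_hand)
  expect_equal(o2$p, 2 * pt(-abs(t_hand), df = 7))

  # zero-variance profile fails with a recorded reason
  gf3 <- fpkm_matrix(rbind(g = rep(2, 9)), samples, "gene")
  o3 <- coexpression_screen(tibble::tibble(lncrna_id = "l", gene_id = "g",
                                           mode = "cis"), lf2, gf3)
  expect_false(o3$passes)
  expect_equal(o3$fail_reason, "zero_variance")
})

test_that("tightening the screen never adds an edge", {
  fix <- default_fixture()
  fp <- default_fpkm()
  gene_fp <- gene_level_fpkm(fp, dplyr::select(fix$annotation$transcripts,
                                               transcript_id, gene_id))
  pairs <- fix$truth$pairs
  loose <- coexpression_screen(pairs, fp, gene_fp, r_cut = 0.6, p_cut = 0.1)
  tight <- coexpression_screen(pairs, fp, gene_fp, r_cut = 0.9, p_cut = 0.01)
  expect_true(all(tight$passes <= loose$passes))
})

test_that("networks carry DE regulation on nodes and reject unknown endpoints", {
  edges <- tibble::tibble(lncrna_id = c("l1", "l2"), gene_id = c("g1", "g2"),
                          mode = c("cis", "trans"), r = c(0.9, 0.95),
                          p = c(0.01, 0.001), passes = TRUE)
  calls <- tibble::tibble(feature_id = c("l1", "l2", "g1", "g2"),
                          call = c("up", "down", "up", "down"))
  net <- build_network(edges, calls)
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$nodes$regulation[net$nodes$id == "g2"], "down")
  expect_equal(net$nodes$kind[net$nodes$id == "l1"], "lncRNA")
  td <- tidy(net)
  expect_equal(td$gene_regulation, c("up", "down"))

  expect_error(build_network(edges, calls[-1, ]), "l1")
  empty <- build_network(edges[0, ], calls)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("the keyword subnetwork filters on annotated term names", {
  edges <- tibble::tibble(lncrna_id = c("l1", "l2"), gene_id = c("g1", "g2"),
                          mode = "cis", r = 0.9, p = 0.01, passes = TRUE)
  calls <- tibble::tibble(feature_id = c("l1", "l2", "g1", "g2"),
                          call = "up")
  net <- build_network(edges, calls)
  terms <- tibble::tibble(gene_id = "g1",
                          term_name = "Skeletal System Development")
  sub <- keyword_subnetwork(net, terms, keywords = "skeletal")
  expect_equal(sub$edges$gene_id, "g1")
  expect_true(all(sub$edges$gene_id %in% net$edges$gene_id))
  # unannotated genes drop out
  expect_false("g2" %in% sub$nodes$id)
})
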