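toy_terms <- function(n_genes = 20, term_genes = paste0("g", 1:5)) {
  tibble::tibble(term_id = "T1", term_name = "toy term",
                 gene_id = term_genes)
}

test_that("hypergeometric p matches combinatorial hand calculations", {
  universe <- paste0("g", 1:20)
  res <- hypergeometric_enrichment(paste0("g", 1:5), universe, toy_terms())
  expect_equal(res$p, 1 / choose(20, 5))
  expect_equal(res$k, 5)
  expect_equal(res$K, 5)

  # term equal to the universe is never enriched
  res_all <- hypergeometric_enrichment(paste0("g", 1:7), universe,
                                       toy_terms(term_genes = universe))
  expect_equal(res_all$p, 1)

  # a set below expectation has upper-tail p >= 0.5
  res_low <- hypergeometric_enrichment(paste0("g", 6:15), universe,
                                       toy_terms())
  expect_gte(res_low$p, 0.5)

  expect_error(
    hypergeometric_enrichment(c("g1", "stranger"), universe, toy_terms()),
    "stranger"
  )
})

test_that("hypergeometric tail equals exact enumeration for small universes", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    universe <- paste0("u", seq_len(N))
    term <- tibble::tibble(term_id = "T", term_name = "t",
                           gene_id = universe[seq_len(K)])
    gene_set <- sample(universe, n)
    k <- sum(gene_set %in% term$gene_id)
    exact <- sum(vapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
    got <- hypergeometric_enrichment(gene_set, universe, term)$p
    expect_equal(got, exact, tolerance = 1e-12)
  }
})

test_that("BH correction in enrichment is order-preserving", {
  universe <- paste0("g", 1:50)
  t2g <- dplyr::bind_rows(
    tibble::tibble(term_id = "A", term_name = "a", gene_id = paste0("g", 1:10)),
    tibble::tibble(term_id = "B", term_name = "b", gene_id = paste0("g", 11:40))
  )
  res <- hypergeometric_enrichment(paste0("g", 1:10), universe, t2g)
  expect_true(all(res$p_corrected >= res$p))
  expect_equal(res$p_corrected, sort(res$p_corrected))
})

test_that("KS enrichment detects concentration in the top ranks", {
  set.seed(32)
  universe <- paste0("g", 1:200)
  scores <- setNames(seq(0.001, 1, length.out = 200), universe)
  t2g <- tibble::tibble(term_id = "TOP", term_name = "top-heavy",
                        gene_id = universe[1:15])
  res <- ks_enrichment(scores, t2g)
  expect_lt(res$ks_p, 0.01)
  expect_true(res$significant)

  # identical distributions give D = 0
  sc <- setNames(rep(c(0.1, 0.5, 0.9), length.out = 30), paste0("h", 1:30))
  t2g0 <- tibble::tibble(term_id = "T0", term_name = "t",
                         gene_id = paste0("h", 1:3))
  res0 <- ks_enrichment(sc[c(paste0("h", 1:3), paste0("h", 4:30))], t2g0)
  expect_equal(res0$D, 0)

  # a term with < 2 universe genes is skipped with a warning
  t2g1 <- tibble::tibble(term_id = "T1", term_name = "t1", gene_id = "g1")
  expect_warning(res1 <- ks_enrichment(scores, t2g1), "skipping")
  expect_equal(nrow(res1), 0L)
})

test_that("KS p-values are roughly uniform under random term membership", {
  set.seed(33)
  universe <- paste0("g", 1:200)
  ps <- vapply(1:100, function(i) {
    scores <- setNames(runif(200), universe)
    t2g <- tibble::tibble(term_id = "R", term_name = "r",
                          gene_id = sample(universe, 20))
    ks_enrichment(scores, t2g)$ks_p
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.12)
  expect_lte(mean(ps <= 0.05), 0.12)
})

test_that("top_terms truncates with a stable term_id tie-break", {
  res <- tibble::tibble(term_id = c("C", "A", "B"),
                        term_name = c("c", "a", "b"),
                        p_corrected = c(0.01, 0.02, 0.02))
  expect_equal(nrow(top_terms(res, n = 20)), 3L)
  expect_equal(top_terms(res, n = 2)$term_id, c("C", "A"))
  expect_equal(top_terms(res)$term_id, c("C", "A", "B"))
  expect_error(top_terms(res, order_by = "zz"), "zz")
})

test_that("category breakdown counts, normalises and handles empty sets", {
  map <- tibble::tibble(gene_id = paste0("g", 1:4), category = "cat1")
  out <- category_breakdown(list(s1 = paste0("g", 1:10)), map)
  expect_equal(out$proportion[out$category == "cat1"], 0.4)
  expect_equal(out$proportion[out$category == "unannotated"], 0.6)
  expect_equal(sum(out$proportion), 1)

  empty <- category_breakdown(list(none = character(0)), map)
  expect_equal(empty$n, 0L)

  set.seed(34)
  sets <- list(a = paste0("g", sample(1:20, 8)),
               b = paste0("g", sample(1:20, 12)))
  map2 <- tibble::tibble(gene_id = paste0("g", 1:15),
                         category = sample(c("x", "y"), 15, replace = TRUE))
  bd <- category_breakdown(sets, map2)
  sums <- tapply(bd$proportion, bd$set, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("the null rejection rate of enrichment stays below its level", {
  set.seed(35)
  universe <- paste0("g", 1:100)
  t2g <- purrr::map_dfr(1:10, function(i)
    tibble::tibble(term_id = paste0("T", i), term_name = paste0("t", i),
                   gene_id = sample(universe, 15)))
  frac <- vapply(1:20, function(i) {
    gs <- sample(universe, 20)
    mean(hypergeometric_enrichment(gs, universe, t2g)$p_corrected <= 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})
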