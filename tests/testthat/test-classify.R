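# a reference with one 3-exon gene on chr1:+ spanning [1000, 5000)
toy_reference <- function() {
  genome_annotation(
    toy_exon_row("ref_t1", "ref_g1", "chr1", "+",
                 c(1000, 2500, 4500), c(1500, 3000, 5000))
  )
}

test_that("positional classes follow the antisense > intronic > lincRNA rules", {
  ref <- toy_reference()
  lnc <- genome_annotation(dplyr::bind_rows(
    # exonic overlap on the opposite strand
    toy_exon_row("as1", "x1", "chr1", "-", c(1200, 2600), c(1600, 2800),
                 biotype = "novel"),
    # entirely within the [1500, 2500) intron, same strand, no exon overlap
    toy_exon_row("in1", "x2", "chr1", "+", c(1600, 2100), c(1800, 2300),
                 biotype = "novel"),
    # far away
    toy_exon_row("li1", "x3", "chr1", "+", c(500000, 500600),
                 c(500400, 500900), biotype = "novel")
  ))
  out <- classify_position(lnc, ref)
  got <- setNames(out$positional_class, out$transcript_id)
  expect_equal(got[["as1"]], "antisense")
  expect_equal(got[["in1"]], "intronic")
  expect_equal(got[["li1"]], "lincRNA")
  expect_equal(out$distance[out$transcript_id == "as1"], 0)
  expect_equal(out$distance[out$transcript_id == "li1"], 500000 - 5000)
  expect_equal(unique(out$nearest_gene_id), "ref_g1")
})

test_that("antisense precedence beats intronic containment", {
  ref <- toy_reference()
  # sits inside the intron but also overlaps an exon antisense
  lnc <- genome_annotation(
    toy_exon_row("both", "x", "chr1", "-", c(1400, 2000), c(1700, 2200),
                 biotype = "novel")
  )
  out <- classify_position(lnc, ref)
  expect_equal(out$positional_class, "antisense")
})

test_that("unknown chromosomes classify as lincRNA with a warning", {
  ref <- toy_reference()
  lnc <- genome_annotation(
    toy_exon_row("offchrom", "x", "chrUn", "+", c(100, 600), c(400, 900),
                 biotype = "novel")
  )
  expect_warning(out <- classify_position(lnc, ref), "chrUn")
  expect_equal(out$positional_class, "lincRNA")
})

test_that("classification recovers the planted classes exactly", {
  fix <- default_fixture()
  cls <- fix$truth$classes
  lnc_ids <- cls$transcript_id[cls$true_class %in%
                                 c("lincRNA", "intronic", "antisense")]
  lnc_ann <- filter_transcripts(fix$annotation, lnc_ids)
  out <- classify_position(lnc_ann, fix$reference)
  merged <- dplyr::inner_join(out, cls, by = "transcript_id")
  expect_equal(merged$positional_class, merged$true_class)
  # partition: one class per lncRNA, counts conserve the input
  expect_equal(nrow(out), length(lnc_ids))
  expect_equal(sum(class_proportions(out)$n), length(lnc_ids))
})

test_that("class proportions round to one decimal and conserve counts", {
  p <- class_proportions(rep(c("lincRNA", "intronic", "antisense"),
                             c(4606, 1131, 1187)))
  expect_equal(p$percent[match(c("lincRNA", "intronic", "antisense"),
                               p$positional_class)],
               c(66.5, 16.3, 17.1))
  expect_equal(sum(p$n), 6924)
  expect_equal(attr(p, "rounding_residue"), -0.1)

  p2 <- class_proportions(rep(c("a", "b", "c"), c(1, 1, 2)))
  expect_equal(sort(p2$percent), c(25, 25, 50))
  expect_equal(class_proportions("only")$percent, 100)
  expect_error(class_proportions(character(0)), "empty")
})

test_that("chromosome shares normalise to one", {
  sizes <- tibble::tibble(chromosome = c("c1", "c2"), length = c(75, 25))
  feats <- tibble::tibble(chromosome = rep(c("c1", "c2"), each = 4))
  d <- chromosome_distribution(feats, sizes)
  expect_equal(d$feature_share, c(0.5, 0.5))
  expect_equal(d$size_share, c(0.75, 0.25))

  feats_one <- tibble::tibble(chromosome = rep("c2", 5))
  d1 <- chromosome_distribution(feats_one, sizes)
  expect_equal(d1$feature_share[d1$chromosome == "c2"], 1)

  set.seed(2)
  for (i in 1:5) {
    sz <- tibble::tibble(chromosome = paste0("k", 1:4),
                         length = sample(1e5:1e6, 4))
    ft <- tibble::tibble(chromosome = sample(sz$chromosome, 50, replace = TRUE))
    dd <- chromosome_distribution(ft, sz)
    expect_equal(sum(dd$feature_share), 1)
    expect_equal(sum(dd$size_share), 1)
  }
})

test_that("exon statistics recount the annotation", {
  ann <- genome_annotation(dplyr::bind_rows(
    toy_exon_row("t1", "g1", "chr1", "+", c(0, 200), c(100, 350)),
    toy_exon_row("t2", "g2", "chr1", "+", c(1000, 1300, 1600),
                 c(1100, 1400, 1750)),
    toy_exon_row("t3", "g3", "chr1", "+", c(3000, 3300, 3600, 3900),
                 c(3100, 3400, 3700, 4000))
  ))
  st <- exon_statistics(ann)
  expect_equal(st$mean_exons, 3)
  expect_equal(sum(st$exon_count_hist$n_transcripts), 3)

  single <- genome_annotation(toy_exon_row("s", "g", "chr1", "+", 0, 150))
  h <- exon_statistics(single)$exon_size_hist
  expect_equal(h$n_exons[h$bin == "[100,200)"], 1L)
  expect_equal(sum(h$n_exons), 1L)

  fix <- default_fixture()
  stf <- exon_statistics(fix$annotation)
  expect_equal(stf$mean_exons,
               nrow(fix$annotation$exons) / nrow(fix$annotation$transcripts))
})

test_that("percentage reproduces printed two-decimal reporting", {
  expect_equal(percentage(1, 3, 2), 33.33)
  expect_equal(percentage(c(1, 1), c(4, 8), 1), c(25, 12.5))
  expect_error(percentage(1, 0), "positive")
})
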