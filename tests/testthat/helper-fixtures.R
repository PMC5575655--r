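# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

# default synthetic dataset (the study-condition fixture), written to a
# temp dir so file-based operations can be exercised too
default_fixture <- function() {
  if (is.null(.fixture_env$fix)) {
    cfg <- synthetic_config(seed = 42)
    dir <- file.path(tempdir(), "lncfunnel-fixture")
    sim <- simulate_dataset(cfg, dir)
    .fixture_env$fix <- c(sim, list(config = cfg, dir = dir))
  }
  .fixture_env$fix
}

# discovery run on the default fixture
default_discovery <- function() {
  if (is.null(.fixture_env$disc)) {
    fix <- default_fixture()
    .fixture_env$disc <- discover_lncrnas(fix$annotation, fix$sequences,
                                          fix$counts)
  }
  .fixture_env$disc
}

default_fpkm <- function() {
  if (is.null(.fixture_env$fpkm)) {
    fix <- default_fixture()
    lengths <- setNames(fix$annotation$transcripts$spliced_length,
                        fix$annotation$transcripts$transcript_id)
    .fixture_env$fpkm <- compute_fpkm(fix$counts, lengths)
  }
  .fixture_env$fpkm
}

default_de <- function() {
  if (is.null(.fixture_env$de)) {
    fix <- default_fixture()
    .fixture_env$de <- de_test(fix$counts, default_fpkm())
  }
  .fixture_env$de
}

# one completed pipeline run on the default fixture
default_run <- function() {
  if (is.null(.fixture_env$run)) {
    fix <- default_fixture()
    out <- file.path(tempdir(), "lncfunnel-run")
    cfgp <- pipeline_config(
      reference_gtf = fix$paths$reference_gtf,
      assembled_gtf = fix$paths$assembled_gtf,
      transcripts_fa = fix$paths$transcripts,
      counts_tsv = fix$paths$counts,
      samples_tsv = fix$paths$samples,
      chrom_sizes_tsv = fix$paths$chrom_sizes,
      term2gene_tsv = fix$paths$term2gene,
      categories_tsv = fix$paths$categories
    )
    res <- run_pipeline(cfgp, out)
    .fixture_env$run <- list(config = cfgp, result = res, dir = out)
  }
  .fixture_env$run
}

# tiny hand-built annotation: one 2-exon gene plus room for constructed
# lncRNAs around it
toy_exon_row <- function(tx, gene, chrom, strand, start, end,
                         biotype = "known_mRNA") {
  tibble::tibble(transcript_id = tx, gene_id = gene, chromosome = chrom,
                 strand = strand, start = start, end = end,
                 biotype = biotype)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force longest-ORF oracle: walk codons from every ATG
orf_oracle <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  atgs <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (atgs[1] == -1) return(0L)
  for (a in atgs) {
    pos <- a + 3L
    len <- 3L
    while (pos + 2L <= n) {
      cod <- substr(s, pos, pos + 2L)
      len <- len + 3L
      if (cod %in% stops) {
        if (len > best) best <- len
        break
      }
      pos <- pos + 3L
    }
  }
  best
}
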