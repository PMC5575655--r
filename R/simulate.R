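#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the structure of a staged bulk RNA-seq lncRNA
#' study: a small multi-chromosome genome; multi-exon protein-coding genes
#' with ATG-to-stop ORFs under a biased codon usage; planted noncoding
#' transcripts in lincRNA, intronic and antisense positions; coding decoys
#' and structurally invalid junk transcripts; and a 3-stage x 3-replicate
#' negative-binomial count matrix with planted fold changes, planted
#' stage-specific features and planted lncRNA-target expression
#' correlations. All downstream ground truth (classes, DE status per
#' contrast, target pairs) is returned alongside the data.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_chromosomes,chromosome_length Genome shape (bp per chromosome).
#' @param n_coding_genes Protein-coding genes (one transcript each).
#' @param n_linc,n_intronic,n_antisense Planted lncRNAs per positional
#'   class.
#' @param n_decoy_coding Novel transcripts with coding-like sequence
#'   (funnel decoys).
#' @param n_junk Novel transcripts violating the structural filters
#'   (< 200 nt or single exon) by construction.
#' @param replicates_per_stage Replicates per developmental stage (stages
#'   are fetus, lamb, adult).
#' @param nb_dispersion Negative-binomial dispersion `d` (variance
#'   `mu + d mu^2`); `0` is the degenerate no-noise limit where every count
#'   equals its mean.
#' @param planted_log2fc Log2 fold change planted in DE features.
#' @param fraction_stage_specific Fraction of lncRNAs expressed in exactly
#'   one stage.
#' @param gene_fraction_stage_specific Same for protein-coding genes.
#' @param fraction_de Fraction of unpaired, non-stage-specific features
#'   given a planted fold change.
#' @param planted_pair_correlation Target Pearson correlation of planted
#'   lncRNA-target pairs across the 9 samples (open interval (-1, 1)).
#' @param n_cis_pairs,n_trans_pairs Planted lncRNA-target pairs by mode.
#' @param min_linc_gap Minimum distance (bp) between a lincRNA and any gene.
#' @param mrna_base_mean,lnc_base_mean,pair_base_mean Baseline mean counts;
#'   lncRNAs sit below mRNAs, mirroring their lower average expression.
#' @param library_size_factor_sd Log-normal sd of per-sample depth factors.
#' @param codon_bias_strength Weight multiplier of preferred codons in
#'   coding ORFs (drives the learnable hexamer/Fickett contrast).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 3,
                             chromosome_length = 1500000,
                             n_coding_genes = 120,
                             n_linc = 30, n_intronic = 15, n_antisense = 15,
                             n_decoy_coding = 25, n_junk = 25,
                             replicates_per_stage = 3,
                             nb_dispersion = 0.05,
                             planted_log2fc = 2,
                             fraction_stage_specific = 0.33,
                             gene_fraction_stage_specific = 0.04,
                             fraction_de = 0.3,
                             planted_pair_correlation = 0.95,
                             n_cis_pairs = 12, n_trans_pairs = 6,
                             min_linc_gap = 2000,
                             mrna_base_mean = 60, lnc_base_mean = 18,
                             pair_base_mean = 120,
                             library_size_factor_sd = 0.08,
                             codon_bias_strength = 8) {
  cfg <- as.list(environment())
  counts_fields <- c("n_chromosomes", "chromosome_length", "n_coding_genes",
                     "n_linc", "n_intronic", "n_antisense", "n_decoy_coding",
                     "n_junk", "replicates_per_stage", "n_cis_pairs",
                     "n_trans_pairs")
  for (f in counts_fields) {
    if (cfg[[f]] < 0) abort(paste0("config field ", f, " must be >= 0"))
  }
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (planted_pair_correlation <= -1 || planted_pair_correlation >= 1) {
    abort("planted_pair_correlation must lie in (-1, 1)")
  }
  if (fraction_stage_specific < 0 || fraction_stage_specific > 1 ||
      fraction_de < 0 || fraction_de > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (n_cis_pairs + n_trans_pairs > n_linc) {
    abort("planted pairs cannot exceed the number of lincRNAs")
  }
  if (n_intronic > n_coding_genes || n_antisense > n_coding_genes) {
    abort("not enough coding genes to host intronic/antisense lncRNAs")
  }
  cfg$stages <- c("fetus", "lamb", "adult")
  structure(cfg, class = "synthetic_config")
}

# 16 preferred codons (GC-leaning, no stops); a fixed set so the coding
# hexamer signature is stable across seeds and learnable by the classifier
preferred_codons <- c("GCC", "GAG", "AAG", "CTG", "GAC", "TTC", "ATC",
                      "GGC", "CAG", "CGC", "ACC", "GTG", "TAC", "AGC",
                      "CCC", "AAC")

stop_codons <- c("TAA", "TAG", "TGA")

codon_pool <- function(strength) {
  b <- c("A", "C", "G", "T")
  all_codons <- do.call(paste0, expand.grid(b, b, b,
                                            KEEP.OUT.ATTRS = FALSE,
                                            stringsAsFactors = FALSE)[, 3:1])
  pool <- setdiff(all_codons, stop_codons)
  w <- if_else(pool %in% preferred_codons, strength, 1)
  list(codons = pool, prob = w / sum(w))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Interval allocator: picks a start for a span of `len` at least `pad` away
# from every occupied interval on the chromosome. `occupied` is a 2-column
# matrix of half-open intervals.
allocate_span <- function(occupied, chrom_len, len, pad) {
  occ <- occupied[order(occupied[, 1]), , drop = FALSE]
  gaps_start <- c(0, occ[, 2])
  gaps_end <- c(occ[, 1], chrom_len)
  width <- gaps_end - gaps_start
  need <- len + 2 * pad
  ok <- which(width >= need)
  if (length(ok) == 0) return(NULL)
  g <- if (length(ok) == 1) ok else sample(ok, 1, prob = width[ok])
  slack <- width[g] - need
  gaps_start[g] + pad + sample.int(slack + 1L, 1) - 1L
}

make_exons <- function(start, exon_lens, intron_lens) {
  starts <- start + cumsum(c(0, head(exon_lens, -1) + intron_lens))
  cbind(start = starts, end = starts + exon_lens)
}

#' Generate the toy genome, annotation and partial ground truth
#'
#' See [synthetic_config()] for what is planted. Coding genes carry designed
#' ORFs (ATG start, stop end, biased codon usage) written into the genome;
#' lncRNA loci keep the uniform-random background sequence; trans-pair
#' target genes carry a reverse-complement segment of their partner lincRNA
#' in the 3' UTR. Placement rules mirror the positional classifier exactly
#' (lincRNAs at least `min_linc_gap` from any gene; intronic lncRNAs
#' strictly inside an intron with no exonic overlap; antisense lncRNAs
#' overlapping an exon on the opposite strand).
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (named character vector of chromosome
#'   sequences), `annotation` (assembled-view [genome_annotation()]: known
#'   mRNAs plus novel transcripts), `reference` (known genes only) and
#'   `truth` (classes, expression plan, DE truth, planted pairs).
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_len <- config$chromosome_length
  # per-base vectors during construction (string surgery on multi-megabase
  # strings copies the whole chromosome per write)
  genome_vec <- setNames(lapply(chroms, function(x)
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)), chroms)
  occupied <- setNames(lapply(chroms, function(x)
    matrix(numeric(0), ncol = 2)), chroms)

  exon_rows <- list()
  add_tx <- function(tx_id, gene_id, chrom, strand, exons, biotype) {
    exon_rows[[length(exon_rows) + 1]] <<- tibble(
      transcript_id = tx_id, gene_id = gene_id, chromosome = chrom,
      strand = strand, start = exons[, 1], end = exons[, 2],
      biotype = biotype
    )
  }

  # ---- protein-coding genes -------------------------------------------
  gene_chrom <- rep(chroms, length.out = config$n_coding_genes)
  gene_meta <- vector("list", config$n_coding_genes)
  for (i in seq_len(config$n_coding_genes)) {
    ch <- gene_chrom[i]
    n_ex <- sample(4:9, 1)
    exon_lens <- sample(120:300, n_ex, replace = TRUE)
    intron_lens <- sample(500:2500, n_ex - 1, replace = TRUE)
    if (i <= config$n_intronic) {
      # reserve a long intron to host an intronic lncRNA
      intron_lens[sample.int(n_ex - 1, 1)] <- 3000L
    }
    span <- sum(exon_lens) + sum(intron_lens)
    start <- allocate_span(occupied[[ch]], chrom_len, span, pad = 3000)
    if (is.null(start)) {
      abort("placement impossible at the requested density; increase chromosome_length or reduce feature counts")
    }
    ex <- make_exons(start, exon_lens, intron_lens)
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("GENE%04d", i)
    occupied[[ch]] <- rbind(occupied[[ch]], c(start, start + span))
    add_tx(sprintf("MRNA%04d", i), gid, ch, strand, ex, "known_mRNA")
    gene_meta[[i]] <- list(gene_id = gid, tx_id = sprintf("MRNA%04d", i),
                           chrom = ch, strand = strand, exons = ex,
                           intron_lens = intron_lens)
  }

  # ---- intronic lncRNAs (inside the reserved introns) ------------------
  for (i in seq_len(config$n_intronic)) {
    gm <- gene_meta[[i]]
    ints <- cbind(gm$exons[-nrow(gm$exons), 2], gm$exons[-1, 1])
    host <- ints[which.max(ints[, 2] - ints[, 1]), ]
    exon_lens <- sample(100:200, 2, replace = TRUE)
    intron_len <- sample(100:300, 1)
    span <- sum(exon_lens) + intron_len
    pad_avail <- (host[2] - host[1]) - span
    stopifnot(pad_avail > 20)
    start <- host[1] + 10 + sample.int(pad_avail - 20, 1)
    ex <- make_exons(start, exon_lens, intron_len)
    add_tx(sprintf("LNCI%04d", i), sprintf("XLOC_I%04d", i), gm$chrom,
           sample(c("+", "-"), 1), ex, "novel")
  }

  # ---- antisense lncRNAs (overlapping an exon, opposite strand) --------
  for (i in seq_len(config$n_antisense)) {
    gm <- gene_meta[[config$n_intronic + i]]
    last_ex <- gm$exons[nrow(gm$exons), ]
    gene_end <- max(gm$exons[, 2])
    e1_start <- max(last_ex[1], last_ex[2] - 150)
    e1 <- c(e1_start, last_ex[2] + 50)
    e2 <- c(gene_end + 400, gene_end + 400 + sample(150:300, 1))
    ex <- cbind(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
    strand <- if (gm$strand == "+") "-" else "+"
    occupied[[gm$chrom]] <- rbind(occupied[[gm$chrom]], c(e1[1], e2[2]))
    add_tx(sprintf("LNCA%04d", i), sprintf("XLOC_A%04d", i), gm$chrom,
           strand, ex, "novel")
  }

  # ---- lincRNAs --------------------------------------------------------
  linc_ids <- sprintf("LINC%04d", seq_len(config$n_linc))
  for (i in seq_len(config$n_linc)) {
    ch <- sample(chroms, 1)
    n_ex <- sample(2:4, 1)
    exon_lens <- sample(150:400, n_ex, replace = TRUE)
    intron_lens <- sample(100:500, max(n_ex - 1, 0), replace = TRUE)
    span <- sum(exon_lens) + sum(intron_lens)
    start <- allocate_span(occupied[[ch]], chrom_len, span,
                           pad = config$min_linc_gap)
    if (is.null(start)) {
      abort("placement impossible at the requested density; increase chromosome_length or reduce feature counts")
    }
    ex <- make_exons(start, exon_lens, intron_lens)
    occupied[[ch]] <- rbind(occupied[[ch]], c(start, start + span))
    add_tx(linc_ids[i], sprintf("XLOC_L%04d", i), ch,
           sample(c("+", "-"), 1), ex, "novel")
  }

  # ---- coding decoys ---------------------------------------------------
  for (i in seq_len(config$n_decoy_coding)) {
    ch <- sample(chroms, 1)
    n_ex <- sample(5:8, 1)
    exon_lens <- sample(150:300, n_ex, replace = TRUE)
    intron_lens <- sample(300:1500, n_ex - 1, replace = TRUE)
    span <- sum(exon_lens) + sum(intron_lens)
    start <- allocate_span(occupied[[ch]], chrom_len, span, pad = 2000)
    if (is.null(start)) {
      abort("placement impossible at the requested density; increase chromosome_length or reduce feature counts")
    }
    ex <- make_exons(start, exon_lens, intron_lens)
    occupied[[ch]] <- rbind(occupied[[ch]], c(start, start + span))
    add_tx(sprintf("DECOY%04d", i), sprintf("XLOC_D%04d", i), ch,
           sample(c("+", "-"), 1), ex, "novel")
  }

  # ---- junk (fails the structural filter by construction) --------------
  for (i in seq_len(config$n_junk)) {
    ch <- sample(chroms, 1)
    if (i %% 2 == 0) {  # single exon, long enough
      ex <- cbind(start = 0, end = sample(300:800, 1))
    } else {            # two exons, spliced length < 200
      l1 <- sample(60:90, 1); l2 <- sample(60:90, 1)
      ex <- make_exons(0, c(l1, l2), sample(100:400, 1))
    }
    span <- max(ex[, 2]) - min(ex[, 1])
    start <- allocate_span(occupied[[ch]], chrom_len, span, pad = 1000)
    if (is.null(start)) {
      abort("placement impossible at the requested density; increase chromosome_length or reduce feature counts")
    }
    ex <- ex + start
    occupied[[ch]] <- rbind(occupied[[ch]], c(start, start + span))
    add_tx(sprintf("JUNK%04d", i), sprintf("XLOC_J%04d", i), ch,
           sample(c("+", "-"), 1), ex, "novel")
  }

  exons <- bind_rows(exon_rows)
  chrom_sizes <- tibble(chromosome = chroms, length = chrom_len)
  annotation <- genome_annotation(exons, chrom_sizes = chrom_sizes)

  # ---- planted pairs (need spans before sequence design) ---------------
  ref_exons <- filter(exons, .data$biotype == "known_mRNA")
  reference <- genome_annotation(ref_exons, chrom_sizes = chrom_sizes)
  linc_tx <- filter(annotation$transcripts, .data$transcript_id %in% linc_ids)
  cis_cand <- cis_targets(linc_tx, reference, window = 100000) %>%
    group_by(.data$lncrna_id) %>%
    arrange(.data$distance, .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup()
  # distinct genes, one pair per lincRNA
  cis_cand <- cis_cand[!duplicated(cis_cand$gene_id), ]
  if (nrow(cis_cand) < config$n_cis_pairs) {
    abort("could not plant the requested number of cis pairs; increase n_linc or gene density")
  }
  cis_pairs <- cis_cand[seq_len(config$n_cis_pairs), ]

  free_lincs <- setdiff(linc_ids, cis_pairs$lncrna_id)
  trans_lincs <- free_lincs[seq_len(config$n_trans_pairs)]
  free_genes <- setdiff(vapply(gene_meta, `[[`, "", "gene_id"),
                        cis_pairs$gene_id)
  trans_genes <- sample(free_genes, config$n_trans_pairs)
  trans_pairs <- tibble(lncrna_id = trans_lincs, gene_id = trans_genes,
                        mode = "trans")

  # ---- designed coding sequences --------------------------------------
  pool <- codon_pool(config$codon_bias_strength)
  lnc_seq_now <- extract_spliced_vec(genome_vec, annotation, linc_ids)
  gene_by_id <- setNames(gene_meta, vapply(gene_meta, `[[`, "", "gene_id"))
  pending_writes <- list()
  tx_tbl <- annotation$transcripts
  coding_tx <- tx_tbl$transcript_id[grepl("^(MRNA|DECOY)", tx_tbl$transcript_id)]
  for (tx in coding_tx) {
    row <- tx_tbl[tx_tbl$transcript_id == tx, ]
    S <- row$spliced_length
    gid <- row$gene_id
    trans_target <- gid %in% trans_pairs$gene_id
    utr3 <- if (trans_target) 180L else max(30L, round(0.1 * S))
    utr5 <- max(30L, round(0.1 * S))
    orf_codons <- floor((S - utr5 - utr3) / 3) - 2L
    stopifnot(orf_codons >= 60)
    body <- paste(sample(pool$codons, orf_codons, replace = TRUE,
                         prob = pool$prob), collapse = "")
    core <- paste0("ATG", body, "TAA")
    utr3_len <- S - utr5 - nchar(core)
    seq <- paste0(random_dna(utr5), core, random_dna(utr3_len))
    if (trans_target) {
      partner <- trans_pairs$lncrna_id[trans_pairs$gene_id == gid]
      seg <- substr(lnc_seq_now[[partner]], 1, 150)
      substr(seq, S - 160L, S - 11L) <- reverse_complement(seg)
    }
    pending_writes[[tx]] <- spliced_write(annotation, tx, seq)
  }
  # apply all designed-sequence writes in one pass per chromosome
  for (ch in chroms) {
    w <- purrr::keep(pending_writes, ~ .x$chrom == ch)
    if (length(w) > 0) {
      genome_vec[[ch]][unlist(lapply(w, `[[`, "idx"))] <-
        unlist(lapply(w, `[[`, "chars"))
    }
  }
  genome <- vapply(genome_vec, paste, character(1), collapse = "")

  # ---- expression plan -------------------------------------------------
  lfc <- config$planted_log2fc
  tx_tbl <- annotation$transcripts
  kind <- case_when(
    grepl("^MRNA", tx_tbl$transcript_id) ~ "mRNA",
    grepl("^LINC", tx_tbl$transcript_id) ~ "lincRNA",
    grepl("^LNCI", tx_tbl$transcript_id) ~ "intronic",
    grepl("^LNCA", tx_tbl$transcript_id) ~ "antisense",
    grepl("^DECOY", tx_tbl$transcript_id) ~ "decoy_coding",
    TRUE ~ "junk"
  )
  classes <- tibble(transcript_id = tx_tbl$transcript_id,
                    gene_id = tx_tbl$gene_id, true_class = kind)

  plan <- tibble(
    feature_id = tx_tbl$transcript_id,
    kind = kind,
    base_log2 = log2(case_when(
      kind == "mRNA" ~ config$mrna_base_mean,
      kind %in% c("lincRNA", "intronic", "antisense") ~ config$lnc_base_mean,
      TRUE ~ config$mrna_base_mean / 2
    )) + rnorm(nrow(tx_tbl), 0, 0.7),
    off_fetus = 0, off_lamb = 0, off_adult = 0,
    pair_id = NA_character_, pair_jitter_sd = 0
  )
  rownames_plan <- setNames(seq_len(nrow(plan)), plan$feature_id)
  set_profile <- function(plan, fid, off) {
    i <- rownames_plan[[fid]]
    plan$off_fetus[i] <- off[1]; plan$off_lamb[i] <- off[2]
    plan$off_adult[i] <- off[3]
    plan
  }

  # paired features: a shared monotone stage profile drives both the DE
  # status and the co-expression of the pair
  pair_tbl <- bind_rows(
    mutate(select(cis_pairs, "lncrna_id", "gene_id", "mode"),
           pair_id = paste0("cis_", row_number())),
    mutate(trans_pairs, pair_id = paste0("trans_", row_number()))
  )
  mrna_of_gene <- setNames(vapply(gene_meta, `[[`, "", "tx_id"),
                           vapply(gene_meta, `[[`, "", "gene_id"))
  for (i in seq_len(nrow(pair_tbl))) {
    dir <- sample(c(-1, 1), 1)
    off <- dir * c(-lfc, 0, lfc)
    l_id <- pair_tbl$lncrna_id[i]
    g_tx <- mrna_of_gene[[pair_tbl$gene_id[i]]]
    for (fid in c(l_id, g_tx)) {
      plan <- set_profile(plan, fid, off)
      j <- rownames_plan[[fid]]
      plan$pair_id[j] <- pair_tbl$pair_id[i]
      plan$base_log2[j] <- log2(config$pair_base_mean) + rnorm(1, 0, 0.3)
    }
  }
  paired_features <- plan$feature_id[!is.na(plan$pair_id)]

  # stage-specific features
  lnc_ids_all <- plan$feature_id[plan$kind %in%
                                   c("lincRNA", "intronic", "antisense")]
  lnc_free <- setdiff(lnc_ids_all, paired_features)
  n_lnc_spec <- round(config$fraction_stage_specific * length(lnc_ids_all))
  n_lnc_spec <- min(n_lnc_spec, length(lnc_free))
  lnc_spec <- sample(lnc_free, n_lnc_spec)
  mrna_ids_all <- plan$feature_id[plan$kind == "mRNA"]
  mrna_free <- setdiff(mrna_ids_all, paired_features)
  n_g_spec <- round(config$gene_fraction_stage_specific * length(mrna_ids_all))
  g_spec <- sample(mrna_free, min(n_g_spec, length(mrna_free)))
  for (fid in c(lnc_spec, g_spec)) {
    st <- sample(1:3, 1)
    off <- rep(-12, 3); off[st] <- 0
    plan <- set_profile(plan, fid, off)
  }

  # unpaired planted-fold-change features
  de_pool <- setdiff(c(lnc_free, mrna_free), c(lnc_spec, g_spec))
  n_extra_de <- round(config$fraction_de * length(de_pool))
  extra_de <- sample(de_pool, n_extra_de)
  for (fid in extra_de) {
    st <- sample(1:3, 1)
    off <- rep(0, 3); off[st] <- sample(c(-lfc, lfc), 1)
    plan <- set_profile(plan, fid, off)
  }

  # DE truth per contrast from the planted profiles
  contrasts <- list(c("fetus", "lamb"), c("lamb", "adult"),
                    c("fetus", "adult"))
  offs <- as.matrix(plan[, c("off_fetus", "off_lamb", "off_adult")])
  colnames(offs) <- config$stages
  de_truth <- purrr::map_dfr(contrasts, function(ct) {
    delta <- offs[, ct[2]] - offs[, ct[1]]
    keep <- abs(delta) > 1
    tibble(feature_id = plan$feature_id[keep],
           contrast = paste0(ct[1], "_vs_", ct[2]),
           direction = if_else(delta[keep] > 0, "up", "down"),
           planted_log2fc = delta[keep])
  })

  truth <- structure(
    list(classes = classes, expression_plan = plan, de = de_truth,
         pairs = pair_tbl, config = config),
    class = "synthetic_truth"
  )
  list(genome = genome, annotation = annotation, reference = reference,
       truth = truth)
}

# spliced sequence of given transcripts straight off the genome strings
extract_spliced <- function(genome, annotation, transcript_ids) {
  out <- setNames(character(length(transcript_ids)), transcript_ids)
  ex_all <- annotation$exons
  for (tx in transcript_ids) {
    ex <- ex_all[ex_all$transcript_id == tx, ]
    g <- genome[[ex$chromosome[1]]]
    chunks <- substring(g, ex$start + 1L, ex$end)
    s <- paste(chunks, collapse = "")
    if (ex$strand[1] == "-") s <- reverse_complement(s)
    out[[tx]] <- s
  }
  out
}

# vector-backed variants used during construction
extract_spliced_vec <- function(genome_vec, annotation, transcript_ids) {
  out <- setNames(character(length(transcript_ids)), transcript_ids)
  ex_all <- annotation$exons
  for (tx in transcript_ids) {
    ex <- ex_all[ex_all$transcript_id == tx, ]
    g <- genome_vec[[ex$chromosome[1]]]
    idx <- unlist(lapply(seq_len(nrow(ex)), function(j)
      seq.int(ex$start[j] + 1L, ex$end[j])))
    s <- paste(g[idx], collapse = "")
    if (ex$strand[1] == "-") s <- reverse_complement(s)
    out[[tx]] <- s
  }
  out
}

# positions and characters of a designed spliced sequence on the genome
# (strand-aware); applied in one batched write per chromosome
spliced_write <- function(annotation, transcript_id, seq) {
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id, ]
  stopifnot(nchar(seq) == sum(ex$end - ex$start))
  genomic <- if (ex$strand[1] == "-") reverse_complement(seq) else seq
  idx <- unlist(lapply(seq_len(nrow(ex)), function(j)
    seq.int(ex$start[j] + 1L, ex$end[j])))
  list(chrom = ex$chromosome[1], idx = idx,
       chars = strsplit(genomic, "", fixed = TRUE)[[1]])
}

#' Extract spliced transcript sequences
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements minus-strand transcripts.
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param annotation A [genome_annotation()] within the genome bounds.
#' @return Named character vector of spliced sequences.
#' @export
generate_transcript_sequences <- function(genome, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  lens <- setNames(nchar(genome), names(genome))
  chk <- annotation$exons %>% mutate(chrom_len = lens[.data$chromosome])
  if (anyNA(chk$chrom_len) || any(chk$end > chk$chrom_len)) {
    abort("exon beyond chromosome end (or unknown chromosome)")
  }
  extract_spliced(genome, annotation,
                  annotation$transcripts$transcript_id)
}

#' Simulate the count matrix from the planted expression plan
#'
#' Counts are negative binomial around per-feature, per-stage means:
#' `mu = 2^(base + stage offset + pair jitter) * sample depth factor`,
#' `var = mu + d mu^2`. At `nb_dispersion = 0` the generator degenerates to
#' noise-free counts equal to (rounded) means. Paired features share their
#' stage profile; an independent per-sample jitter is added to each endpoint,
#' sized so the expected sample-level correlation of the pair matches
#' `planted_pair_correlation` (given the profile variance and the expected
#' count noise).
#'
#' @param config A [synthetic_config()].
#' @param truth The `synthetic_truth` from [generate_genome_and_annotation()].
#' @return A [count_matrix()] over all transcripts, samples named
#'   `stage_replicate`.
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  withr::with_seed(config$seed + 7919L, simulate_counts_impl(config, truth))
}

simulate_counts_impl <- function(config, truth) {
  plan <- truth$expression_plan
  stages <- config$stages
  reps <- config$replicates_per_stage
  samples <- tibble(
    sample = paste(rep(stages, each = reps),
                   rep(seq_len(reps), length(stages)), sep = "_"),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), length(stages))
  )
  n_s <- nrow(samples)
  sf <- exp(rnorm(n_s, 0, config$library_size_factor_sd))
  offs <- as.matrix(plan[, c("off_fetus", "off_lamb", "off_adult")])
  colnames(offs) <- stages
  log2mu <- offs[, samples$stage, drop = FALSE]  # features x samples
  log2mu <- log2mu + plan$base_log2

  # jitter for paired endpoints, calibrated to the target pair correlation
  r <- config$planted_pair_correlation
  d <- config$nb_dispersion
  paired <- which(!is.na(plan$pair_id))
  if (length(paired) > 0 && abs(r) > 0) {
    for (i in paired) {
      prof <- offs[i, samples$stage]
      V <- mean((prof - mean(prof))^2)
      mu_s <- 2^(plan$base_log2[i] + prof)
      var_c <- (1 / log(2))^2 * mean(1 / mu_s + d)
      b2 <- max(0, V * (1 - abs(r)) / abs(r) - var_c)
      log2mu[i, ] <- log2mu[i, ] + rnorm(n_s, 0, sqrt(b2))
    }
  }
  mu <- sweep(2^log2mu, 2, sf, "*")
  counts <- if (d == 0) {
    round(mu)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / d), nrow = nrow(mu))
  }
  rownames(counts) <- plan$feature_id
  colnames(counts) <- samples$sample
  storage.mode(counts) <- "integer"
  count_matrix(counts, samples)
}

#' Generate and write the complete synthetic fixture set
#'
#' Runs [generate_genome_and_annotation()], [generate_transcript_sequences()]
#' and [simulate_counts()] and writes genome FASTA, reference and assembled
#' GTF, spliced transcript FASTA, counts and sample-metadata TSV, the
#' ground-truth tables and a toy term-to-gene map plus functional-category
#' map with planted muscle-term enrichment on the planted target genes.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with all in-memory objects and a `paths`
#'   element naming every written file.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome_and_annotation(config)
  seqs <- generate_transcript_sequences(gen$genome, gen$annotation)
  counts <- simulate_counts(config, gen$truth)
  maps <- withr::with_seed(config$seed + 104729L,
                           make_term_maps(gen, config))

  p <- list(
    genome = file.path(dir, "genome.fa"),
    reference_gtf = file.path(dir, "reference.gtf"),
    assembled_gtf = file.path(dir, "assembled.gtf"),
    transcripts = file.path(dir, "transcripts.fa"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    truth_classes = file.path(dir, "truth_classes.tsv"),
    truth_de = file.path(dir, "truth_de.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    term2gene = file.path(dir, "term2gene.tsv"),
    categories = file.path(dir, "categories.tsv")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$genome), p$genome)
  write_gtf(gen$reference, p$reference_gtf)
  write_gtf(gen$annotation, p$assembled_gtf, class_code = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), p$transcripts)
  readr::write_tsv(as_tibble(counts$counts, rownames = "feature_id"),
                   p$counts, progress = FALSE)
  readr::write_tsv(counts$samples, p$samples, progress = FALSE)
  readr::write_tsv(gen$annotation$chrom_sizes, p$chrom_sizes, progress = FALSE)
  readr::write_tsv(gen$truth$classes, p$truth_classes, progress = FALSE)
  readr::write_tsv(gen$truth$de, p$truth_de, progress = FALSE)
  readr::write_tsv(gen$truth$pairs, p$truth_pairs, progress = FALSE)
  readr::write_tsv(maps$term2gene, p$term2gene, progress = FALSE)
  readr::write_tsv(maps$categories, p$categories, progress = FALSE)

  invisible(list(genome = gen$genome, annotation = gen$annotation,
                 reference = gen$reference, truth = gen$truth,
                 sequences = seqs, counts = counts,
                 term2gene = maps$term2gene, categories = maps$categories,
                 paths = p))
}

#' Expression-only ground truths for statistical calibration
#'
#' Lightweight companions to [generate_genome_and_annotation()] for
#' calibration studies that need counts but no genome:
#' `synthetic_null_truth()` builds a flat expression plan (no planted fold
#' changes, no stage specificity, no pairs) for type-I-error checks of the
#' differential-expression statistic; `synthetic_pair_truth()` builds a plan
#' of `n_pairs` lncRNA-gene pairs sharing the planted monotone stage profile,
#' for checking that realised pair correlations match
#' `planted_pair_correlation`.
#'
#' @param config A [synthetic_config()].
#' @param n_features Number of flat features in the null plan.
#' @param n_pairs Number of planted pairs.
#' @param base_mean Baseline mean count of null features.
#' @param base_sd Log2 sd of baseline means across features (0 makes every
#'   feature's mean exactly `base_mean`).
#' @return A `synthetic_truth` accepted by [simulate_counts()].
#' @export
synthetic_null_truth <- function(config, n_features = 200, base_mean = 50,
                                 base_sd = 0.7) {
  ids <- sprintf("FEAT%04d", seq_len(n_features))
  base <- withr::with_seed(config$seed + 17L,
                           log2(base_mean) + rnorm(n_features, 0, base_sd))
  plan <- tibble(
    feature_id = ids, kind = "mRNA", base_log2 = base,
    off_fetus = 0, off_lamb = 0, off_adult = 0,
    pair_id = NA_character_, pair_jitter_sd = 0
  )
  structure(
    list(classes = tibble(transcript_id = ids, gene_id = ids,
                          true_class = "mRNA"),
         expression_plan = plan,
         de = plan[0, c("feature_id")], pairs = tibble(), config = config),
    class = "synthetic_truth"
  )
}

#' @rdname synthetic_null_truth
#' @export
synthetic_pair_truth <- function(config, n_pairs = 100) {
  lfc <- config$planted_log2fc
  lnc <- sprintf("PLNC%04d", seq_len(n_pairs))
  gene <- sprintf("PGENE%04d", seq_len(n_pairs))
  dirs <- withr::with_seed(config$seed + 29L,
                           sample(c(-1, 1), n_pairs, replace = TRUE))
  base <- withr::with_seed(config$seed + 31L,
                           log2(config$pair_base_mean) +
                             rnorm(2 * n_pairs, 0, 0.3))
  plan <- tibble(
    feature_id = c(lnc, gene),
    kind = rep(c("lincRNA", "mRNA"), each = n_pairs),
    base_log2 = base,
    off_fetus = rep(-lfc * dirs, 2),
    off_lamb = 0,
    off_adult = rep(lfc * dirs, 2),
    pair_id = rep(paste0("pair_", seq_len(n_pairs)), 2),
    pair_jitter_sd = 0
  )
  structure(
    list(classes = tibble(transcript_id = plan$feature_id,
                          gene_id = plan$feature_id,
                          true_class = plan$kind),
         expression_plan = plan,
         de = plan[0, c("feature_id")],
         pairs = tibble(lncrna_id = lnc, gene_id = gene, mode = "cis",
                        pair_id = paste0("pair_", seq_len(n_pairs))),
         config = config),
    class = "synthetic_truth"
  )
}

make_term_maps <- function(gen, config) {
  genes <- gen$reference$genes$gene_id
  target_genes <- unique(gen$truth$pairs$gene_id)
  muscle_terms <- c("muscle organ development", "skeletal system development",
                    "myoblast differentiation", "muscle contraction",
                    "skeletal muscle cell differentiation",
                    "muscle cell cellular homeostasis")
  generic_terms <- c("metabolic process", "signal transduction",
                     "immune response", "cell cycle", "ion transport",
                     "transcription regulation", "apoptotic process",
                     "lipid metabolic process", "translation",
                     "cytoskeleton organization", "response to stimulus",
                     "organ morphogenesis")
  rows <- list()
  for (i in seq_along(muscle_terms)) {
    # planted enrichment: muscle terms concentrate on planted target genes
    # (random membership when nothing is planted)
    members <- if (length(target_genes) > 0) {
      n_t <- max(1, round(0.6 * length(target_genes)))
      unique(c(sample(target_genes, n_t), sample(genes, 4)))
    } else {
      sample(genes, min(8, length(genes)))
    }
    rows[[length(rows) + 1]] <- tibble(
      term_id = sprintf("TOY:M%03d", i), term_name = muscle_terms[i],
      gene_id = members)
  }
  for (i in seq_along(generic_terms)) {
    members <- sample(genes, sample(10:25, 1))
    rows[[length(rows) + 1]] <- tibble(
      term_id = sprintf("TOY:G%03d", i), term_name = generic_terms[i],
      gene_id = members)
  }
  categories <- tibble(
    gene_id = genes,
    category = sample(c("General function prediction only",
                        "Signal transduction mechanisms", "Cytoskeleton",
                        "Amino acid transport and metabolism",
                        "Carbohydrate transport and metabolism",
                        "Energy production and conversion",
                        "Inorganic ion transport and metabolism"),
                      length(genes), replace = TRUE,
                      prob = c(0.3, 0.15, 0.1, 0.12, 0.12, 0.11, 0.1))
  )
  list(term2gene = bind_rows(rows), categories = categories)
}
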