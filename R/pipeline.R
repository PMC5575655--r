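#' Pipeline configuration
#'
#' A single validated configuration object holding every input path and
#' every analysis threshold, each defaulting to the pipeline's standard
#' value: structural floors (200 nt, 2 exons), FPKM floor 0.1, FDR 0.05,
#' |log2FC| 1, cis window 100 kb, co-expression screen r > 0.8 and p < 0.05,
#' enrichment cut 0.05. Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param reference_gtf,assembled_gtf,transcripts_fa,counts_tsv,samples_tsv
#'   Input paths (required at [run_pipeline()] time).
#' @param chrom_sizes_tsv,term2gene_tsv,categories_tsv Optional inputs.
#' @param min_length,min_exons Structural filter floors.
#' @param fpkm_floor Expression floor (strict).
#' @param orf_coding_min ORF-rule coding threshold (nt).
#' @param methods Enabled coding-potential methods.
#' @param fdr_cut,lfc_cut DE calling thresholds (strict).
#' @param pseudocount Fold-change pseudocount.
#' @param cis_window Cis target window (bp).
#' @param trans_threshold,trans_window Trans complementarity screen.
#' @param r_cut,p_cut Co-expression screen thresholds.
#' @param enrich_alpha Enrichment significance cut (inclusive).
#' @param keywords Keyword list for the muscle subnetwork.
#' @param expressed_floor Stage-specificity expression floor.
#' @param seed Seed for the (only) stochastic step, classifier training
#'   shuffles.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_gtf = NULL, assembled_gtf = NULL,
                            transcripts_fa = NULL, counts_tsv = NULL,
                            samples_tsv = NULL, chrom_sizes_tsv = NULL,
                            term2gene_tsv = NULL, categories_tsv = NULL,
                            min_length = 200, min_exons = 2,
                            fpkm_floor = 0.1, orf_coding_min = 300,
                            methods = c("orf", "cpat", "cnci"),
                            fdr_cut = 0.05, lfc_cut = 1, pseudocount = 0.01,
                            cis_window = 100000,
                            trans_threshold = 0.9, trans_window = 100,
                            r_cut = 0.8, p_cut = 0.05,
                            enrich_alpha = 0.05,
                            keywords = c("myoblast", "muscle development",
                                         "skeletal development"),
                            expressed_floor = 0.1,
                            seed = 1L) {
  cfg <- as.list(environment())
  in01 <- c("fpkm_floor", "fdr_cut", "p_cut", "enrich_alpha",
            "trans_threshold")
  for (f in in01) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("config field ", f, " must lie in [0, 1]"))
    }
  }
  if (r_cut < -1 || r_cut > 1) abort("r_cut must lie in [-1, 1]")
  if (min_length < 1 || min_exons < 1 || cis_window < 0 || lfc_cut < 0) {
    abort("thresholds out of valid range")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — discover, classify, quantify, detest,
#' network, enrich — writing every stage's tables under `out_dir` together
#' with a manifest (input checksums, configuration, stage-by-stage counts).
#' A stage failure aborts with the stage name; partial outputs are retained.
#' Reruns with identical inputs, configuration and seed are bit-identical.
#'
#' @param config A [pipeline_config()] with all required input paths set.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  required <- c("reference_gtf", "assembled_gtf", "transcripts_fa",
                "counts_tsv", "samples_tsv")
  for (f in required) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(paste0("required input missing or not found: ", f))
    }
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  completed <- character(0)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }

  # ---- inputs ----------------------------------------------------------
  chrom_sizes <- NULL
  if (!is.null(config$chrom_sizes_tsv)) {
    chrom_sizes <- readr::read_tsv(config$chrom_sizes_tsv,
                                   show_col_types = FALSE, progress = FALSE)
  }
  reference <- stage("discover",
                     read_gtf(config$reference_gtf, "reference",
                              chrom_sizes = chrom_sizes))
  assembled <- stage("discover",
                     read_gtf(config$assembled_gtf, "assembled",
                              chrom_sizes = chrom_sizes,
                              reference = reference))
  seqs <- stage("discover", {
    s <- Biostrings::readDNAStringSet(config$transcripts_fa)
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  })
  counts <- stage("discover",
                  read_counts(config$counts_tsv, config$samples_tsv))

  # ---- discover --------------------------------------------------------
  discovery <- stage("discover", discover_lncrnas(
    assembled, seqs, counts,
    min_length = config$min_length, min_exons = config$min_exons,
    fpkm_floor = config$fpkm_floor, orf_coding_min = config$orf_coding_min,
    methods = config$methods, seed = config$seed
  ))
  tsv(as_tibble(discovery), "candidates.tsv")
  tsv(discovery_funnel(discovery), "funnel.tsv")
  lnc_ids <- discovery$transcript_id[discovery$passed]
  completed <- c(completed, "discover")

  # ---- classify --------------------------------------------------------
  classified <- stage("classify", {
    lnc_ann <- filter_transcripts(assembled, lnc_ids)
    classify_position(lnc_ann, reference)
  })
  tsv(classified, "classified.tsv")
  tsv(class_proportions(classified), "class_proportions.tsv")
  if (!is.null(chrom_sizes)) {
    lnc_tx <- filter(assembled$transcripts, .data$transcript_id %in% lnc_ids)
    tsv(chromosome_distribution(lnc_tx, chrom_sizes),
        "chromosome_distribution.tsv")
  }
  completed <- c(completed, "classify")

  # ---- quantify --------------------------------------------------------
  quant <- stage("quantify", {
    lengths <- setNames(assembled$transcripts$spliced_length,
                        assembled$transcripts$transcript_id)
    tx_fpkm <- compute_fpkm(counts, lengths)
    tx2gene <- select(assembled$transcripts, "transcript_id", "gene_id")
    gene_fpkm <- gene_level_fpkm(tx_fpkm, tx2gene)
    list(tx_fpkm = tx_fpkm, gene_fpkm = gene_fpkm, tx2gene = tx2gene)
  })
  tsv(tidy(quant$tx_fpkm), "fpkm_transcripts.tsv")
  tsv(tidy(quant$gene_fpkm), "fpkm_genes.tsv")
  for (st in unique(counts$samples$stage)) {
    rc <- replicate_correlation(quant$tx_fpkm, st)
    tsv(as_tibble(rc, rownames = "replicate"),
        paste0("replicate_correlation_", st, ".tsv"))
  }
  lnc_spec <- stage("quantify", {
    lv <- quant$tx_fpkm$values[lnc_ids, , drop = FALSE]
    stage_specific_features(fpkm_matrix(lv, counts$samples, "lncRNA"),
                            expressed_floor = config$expressed_floor)
  })
  tsv(lnc_spec, "stage_specificity_lncrna.tsv")
  completed <- c(completed, "quantify")

  # ---- detest ----------------------------------------------------------
  ref_gene_ids <- filter(reference$genes,
                         .data$biotype == "protein_coding")$gene_id
  de <- stage("detest", {
    lnc_counts <- count_matrix(counts$counts[lnc_ids, , drop = FALSE],
                               counts$samples)
    lnc_fpkm <- fpkm_matrix(quant$tx_fpkm$values[lnc_ids, , drop = FALSE],
                            counts$samples, "lncRNA")
    known_tx <- filter(assembled$transcripts, .data$biotype == "known_mRNA")
    gcounts <- rowsum(counts$counts[known_tx$transcript_id, , drop = FALSE],
                      group = known_tx$gene_id)
    gene_counts <- count_matrix(gcounts[order(rownames(gcounts)), ,
                                        drop = FALSE], counts$samples)
    gf <- quant$gene_fpkm$values[rownames(gene_counts$counts), , drop = FALSE]
    list(
      lnc = de_test(lnc_counts, lnc_fpkm, fdr_cut = config$fdr_cut,
                    lfc_cut = config$lfc_cut,
                    pseudocount = config$pseudocount),
      gene = de_test(gene_counts, fpkm_matrix(gf, counts$samples, "gene"),
                     fdr_cut = config$fdr_cut, lfc_cut = config$lfc_cut,
                     pseudocount = config$pseudocount),
      lnc_fpkm = lnc_fpkm
    )
  })
  tsv(de$lnc, "de_lncrna.tsv")
  tsv(de$gene, "de_genes.tsv")
  de_sets <- split(filter(de$lnc, .data$call != "ns")$feature_id,
                   filter(de$lnc, .data$call != "ns")$contrast)
  contrast_names <- unique(de$lnc$contrast)
  de_sets <- lapply(setNames(contrast_names, contrast_names),
                    function(ct) de_sets[[ct]] %||% character(0))
  tsv(venn_partition(de_sets), "venn_lncrna.tsv")
  de_lnc_ids <- unique(unlist(de_sets))
  if (length(de_lnc_ids) >= 2) {
    cl <- hierarchical_cluster(
      log10(de$lnc_fpkm$values[de_lnc_ids, , drop = FALSE] + 1))
    tsv(tibble(order = seq_along(cl$leaves), feature_id = cl$leaves),
        "cluster_leaves_lncrna.tsv")
  }
  completed <- c(completed, "detest")

  # ---- network ---------------------------------------------------------
  term2gene <- if (!is.null(config$term2gene_tsv)) {
    read_term_map(config$term2gene_tsv)
  }
  networks <- stage("network", {
    out <- list()
    for (ct in contrast_names) {
      lnc_de_ct <- filter(de$lnc, .data$contrast == ct, .data$call != "ns")
      gene_de_ct <- filter(de$gene, .data$contrast == ct, .data$call != "ns")
      lnc_tx <- filter(assembled$transcripts,
                       .data$transcript_id %in% lnc_de_ct$feature_id)
      cis <- cis_targets(lnc_tx, reference, window = config$cis_window)
      cis <- filter(cis, .data$gene_id %in% gene_de_ct$feature_id)
      trans <- if (nrow(lnc_tx) > 0 && nrow(gene_de_ct) > 0) {
        g2tx <- filter(assembled$transcripts,
                       .data$biotype == "known_mRNA",
                       .data$gene_id %in% gene_de_ct$feature_id)
        mseqs <- setNames(seqs[g2tx$transcript_id], g2tx$gene_id)
        trans_targets(seqs[lnc_tx$transcript_id], mseqs,
                      score_threshold = config$trans_threshold,
                      window = config$trans_window)
      } else {
        tibble(lncrna_id = character(0), gene_id = character(0),
               mode = character(0), score = numeric(0))
      }
      pairs <- bind_rows(select(cis, "lncrna_id", "gene_id", "mode"),
                         select(trans, "lncrna_id", "gene_id", "mode")) %>%
        distinct(.data$lncrna_id, .data$gene_id, .keep_all = TRUE)
      screened <- if (nrow(pairs) > 0) {
        coexpression_screen(pairs, de$lnc_fpkm, quant$gene_fpkm,
                            r_cut = config$r_cut, p_cut = config$p_cut)
      } else {
        mutate(pairs, r = numeric(0), p = numeric(0),
               passes = logical(0), fail_reason = character(0))
      }
      calls <- bind_rows(
        select(lnc_de_ct, "feature_id", "call"),
        select(gene_de_ct, "feature_id", "call")
      )
      net <- build_network(screened, calls)
      tsv(screened, paste0("pairs_", ct, ".tsv"))
      write_network(net, file.path(out_dir, paste0("network_", ct, ".sif")),
                    "sif")
      write_network(net,
                    file.path(out_dir, paste0("network_", ct, ".graphml")),
                    "graphml")
      if (!is.null(term2gene)) {
        sub <- keyword_subnetwork(net, term2gene, config$keywords)
        write_network(sub,
                      file.path(out_dir, paste0("network_muscle_", ct, ".sif")),
                      "sif")
        out[[ct]] <- list(network = net, screened = screened, muscle = sub)
      } else {
        out[[ct]] <- list(network = net, screened = screened)
      }
    }
    out
  })
  completed <- c(completed, "network")

  # ---- enrich ----------------------------------------------------------
  enrich <- NULL
  if (!is.null(term2gene)) {
    enrich <- stage("enrich", {
      out <- list()
      universe <- ref_gene_ids
      for (ct in contrast_names) {
        targets <- unique(networks[[ct]]$screened$gene_id)
        targets <- intersect(targets, universe)
        hyper <- if (length(targets) > 0) {
          hypergeometric_enrichment(targets, universe, term2gene,
                                    alpha = config$enrich_alpha)
        } else {
          NULL
        }
        scores <- setNames(rep(1, length(universe)), universe)
        gde <- filter(de$gene, .data$contrast == ct)
        scores[gde$feature_id[gde$feature_id %in% universe]] <-
          gde$p[gde$feature_id %in% universe]
        ks <- ks_enrichment(scores, term2gene, alpha = config$enrich_alpha)
        if (!is.null(hyper)) {
          tsv(hyper, paste0("enrichment_hyper_", ct, ".tsv"))
          tsv(top_terms(hyper), paste0("enrichment_top_", ct, ".tsv"))
        }
        tsv(ks, paste0("enrichment_ks_", ct, ".tsv"))
        out[[ct]] <- list(hyper = hyper, ks = ks)
      }
      if (!is.null(config$categories_tsv)) {
        cats <- readr::read_tsv(config$categories_tsv,
                                show_col_types = FALSE, progress = FALSE)
        sets <- lapply(setNames(contrast_names, contrast_names), function(ct)
          unique(networks[[ct]]$screened$gene_id))
        tsv(category_breakdown(sets, cats), "category_breakdown.tsv")
      }
      out
    })
    completed <- c(completed, "enrich")
  }

  # ---- manifest --------------------------------------------------------
  input_files <- purrr::compact(config[c("reference_gtf", "assembled_gtf",
                                         "transcripts_fa", "counts_tsv",
                                         "samples_tsv", "chrom_sizes_tsv",
                                         "term2gene_tsv", "categories_tsv")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("lncfunnel")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(input_files))),
    completed_stages = completed,
    funnel = as.list(setNames(discovery_funnel(discovery)$n,
                              discovery_funnel(discovery)$stage)),
    n_lncrna = length(lnc_ids),
    de_lncrna_per_contrast = lapply(
      setNames(contrast_names, contrast_names), function(ct)
        as.list(table(filter(de$lnc, .data$contrast == ct,
                             .data$call != "ns")$call))),
    network_edges = lapply(setNames(contrast_names, contrast_names),
                           function(ct)
                             nrow(networks[[ct]]$network$edges))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(discovery = discovery, classified = classified,
                 quant = quant, de = de, networks = networks,
                 enrich = enrich, manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a completed pipeline run
#'
#' Reads the tables a [run_pipeline()] call wrote and produces one
#' machine-readable summary table plus a short human-readable report.
#' Incomplete runs are summarised as far as possible and flagged.
#'
#' @param run_dir The pipeline output directory.
#' @return List with `summary` (tibble of `metric`, `value`) and `report`
#'   (character lines); the report is also written to
#'   `file.path(run_dir, "report.txt")` and the summary to `summary.tsv`.
#' @export
summarize_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) abort("no manifest.json; not a run directory?")
  manifest <- jsonlite::read_json(manifest_path)
  complete <- length(manifest$completed_stages) >= 5
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1]] <<- tibble(metric = metric,
                                        value = as.character(value))
  }
  for (s in names(manifest$funnel)) {
    add(paste0("funnel_", s), manifest$funnel[[s]])
  }
  cp_path <- file.path(run_dir, "class_proportions.tsv")
  report <- c("lncRNA pipeline run summary",
              paste0("completed stages: ",
                     paste(unlist(manifest$completed_stages),
                           collapse = ", ")))
  if (!complete) report <- c(report, "WARNING: run incomplete")
  if (file.exists(cp_path)) {
    cp <- readr::read_tsv(cp_path, show_col_types = FALSE, progress = FALSE)
    # recompute percentages from counts so the report is self-consistent
    cp$percent <- round(cp$n / sum(cp$n) * 100, 1)
    for (i in seq_len(nrow(cp))) {
      add(paste0("class_", cp$positional_class[i], "_n"), cp$n[i])
      add(paste0("class_", cp$positional_class[i], "_pct"), cp$percent[i])
      report <- c(report, sprintf("  %s: %d (%.1f%%)",
                                  cp$positional_class[i], cp$n[i],
                                  cp$percent[i]))
    }
  }
  for (ct in names(manifest$de_lncrna_per_contrast)) {
    calls <- manifest$de_lncrna_per_contrast[[ct]]
    add(paste0("de_lncrna_up_", ct), calls$up %||% 0)
    add(paste0("de_lncrna_down_", ct), calls$down %||% 0)
    report <- c(report, sprintf("  %s: %s up, %s down lncRNAs", ct,
                                calls$up %||% 0, calls$down %||% 0))
  }
  for (ct in names(manifest$network_edges)) {
    add(paste0("network_edges_", ct), manifest$network_edges[[ct]])
  }
  summary <- bind_rows(rows)
  readr::write_tsv(summary, file.path(run_dir, "summary.tsv"),
                   progress = FALSE)
  writeLines(report, file.path(run_dir, "report.txt"))
  list(summary = summary, report = report)
}
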