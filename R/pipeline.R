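# End-to-end orchestration: simulate (or load) -> classify peaks ->
# differential expression -> integration -> qPCR, with a summary report
# that mirrors the per-comparison result tables of a caste study
# (unique / differential peak counts, category distributions and their
# chi-squared test, DEG/DPG counts and overlap, signal-expression
# correlation, TSS metaprofile, qPCR verification).

#' Write all simulator outputs for one run to disk
#'
#' Produces the on-disk dataset a real study would start from: GFF3 gene
#' models, one BED per caste x replicate, a counts TSV, a Ct TSV, caste
#' coverage bedGraphs, and the ground-truth manifest JSON.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @param n_qpcr_genes how many planted DE genes to assay by qPCR.
#' @return invisibly, a list with the simulated objects and all file
#'   paths (`paths$gff`, `paths$beds`, `paths$counts`, `paths$ct`,
#'   `paths$truth`, `paths$coverage`).
#' @export
simulate_dataset <- function(config, outdir, n_qpcr_genes = 3) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  pk <- simulate_peaks(config, genome)
  ex <- simulate_expression(config, genome, pk$truth)
  truth <- ex$truth
  de_genes <- truth$genes$gene_id[truth$genes$de]
  qpcr_targets <- utils::head(de_genes, n_qpcr_genes)
  ct <- if (length(qpcr_targets)) simulate_qpcr(truth, qpcr_targets, config)
        else NULL

  paths <- list(gff = file.path(outdir, "genome.gff3"),
                counts = file.path(outdir, "counts.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_gff3(genome, paths$gff)
  write_counts(ex$counts, paths$counts)
  beds <- character(0)
  for (caste in unique(pk$peaks$caste)) {
    for (r in sort(unique(pk$peaks$replicate[pk$peaks$caste == caste]))) {
      p <- file.path(outdir, sprintf("%s_rep%d.bed", caste, r))
      write_bed(pk$peaks[pk$peaks$caste == caste & pk$peaks$replicate == r, ], p)
      beds[sprintf("%s_rep%d", caste, r)] <- p
    }
  }
  paths$beds <- beds
  cov_paths <- character(0)
  for (caste in unique(pk$peaks$caste)) {
    cp <- file.path(outdir, sprintf("%s_coverage.bedgraph", caste))
    write_bedgraph(peak_coverage(pk$peaks, caste, config$chrom_length), cp)
    cov_paths[caste] <- cp
  }
  paths$coverage <- cov_paths
  if (!is.null(ct)) {
    paths$ct <- file.path(outdir, "qpcr_ct.tsv")
    write_ct_table(ct, paths$ct)
  }
  write_truth_manifest(truth, paths$truth)
  invisible(list(genome = genome, peaks = pk$peaks, counts = ex$counts,
                 groups = ex$groups, gene_lengths = ex$gene_lengths,
                 ct = ct, truth = truth, qpcr_targets = qpcr_targets,
                 paths = paths))
}

#' Assemble a pipeline run configuration
#'
#' @param seed master seed for the run.
#' @param sim list of [simulation_config()] overrides (ignored when
#'   `inputs` is given).
#' @param inputs optional list of input paths for a data-backed run:
#'   `gff`, `peak_manifest` (TSV with columns `caste`, `replicate`,
#'   `path`, or a data.frame), `counts`, and optionally `ct`. Exactly one
#'   of simulator settings or input paths drives a run.
#' @param fc_threshold,alpha differential-peak thresholds.
#' @param deg_threshold adjusted-p DEG cutoff.
#' @param promoter_upstream,promoter_downstream promoter window.
#' @param prior_df dispersion moderation, see [estimate_dispersion()].
#' @param qpcr_control control group label for the 2^-ddCt baseline.
#' @param n_qpcr_genes planted DE genes to assay (simulator-backed runs).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = list(), inputs = NULL,
                       fc_threshold = 2, alpha = 0.05, deg_threshold = 0.05,
                       promoter_upstream = 2000, promoter_downstream = 200,
                       prior_df = 20, qpcr_control = "W", n_qpcr_genes = 3) {
  check_number(fc_threshold, "fc_threshold", min = 0)
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(deg_threshold, "deg_threshold", min = 0, max = 1)
  if (!is.null(inputs) && length(sim)) {
    stopf("give either simulator settings or input paths, not both")
  }
  structure(list(seed = as.integer(seed), sim = sim, inputs = inputs,
                 fc_threshold = fc_threshold, alpha = alpha,
                 deg_threshold = deg_threshold,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 prior_df = prior_df, qpcr_control = qpcr_control,
                 n_qpcr_genes = n_qpcr_genes),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; the `sim` block holds
#' [simulation_config()] overrides.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  msg <- sprintf("[%s] done in %.2fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(msg)
  cat(msg, "\n", file = log, append = TRUE)
  res
}

#' Run the full caste-comparison pipeline
#'
#' Simulator-backed runs write the synthetic dataset to
#' `<outdir>/inputs/` and then process it through the same file-based
#' readers a data-backed run uses. Stages: consensus + unique/differential
#' classification + feature annotation; category distribution chi-squared
#' tests; NB differential expression; peak-gene linking, DEG/DPG overlap
#' and signal-expression correlation; TSS metaprofile; qPCR 2^-ddCt
#' verification. Every count in the summary report is cross-checked
#' against the corresponding output table, and the run fails loudly on
#' any mismatch. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return invisibly, a list with `report` (also written as
#'   `report.json` + `summary.txt`), the stage objects, and file paths.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, "run.log")
  cat("casteChIP pipeline run\n", file = log)

  truth <- NULL
  if (is.null(config$inputs)) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = config$seed), config$sim))
    ds <- pipeline_stage("simulate", log, {
      simulate_dataset(sim_cfg, file.path(outdir, "inputs"),
                       n_qpcr_genes = config$n_qpcr_genes)
    })
    inputs <- list(gff = ds$paths$gff,
                   peak_manifest = data.frame(
                     caste = sub("_rep.*$", "", names(ds$paths$beds)),
                     replicate = as.integer(sub("^.*_rep", "", names(ds$paths$beds))),
                     path = unname(ds$paths$beds), stringsAsFactors = FALSE),
                   counts = ds$paths$counts, ct = ds$paths$ct,
                   coverage = ds$paths$coverage)
    truth <- ds$truth
  } else {
    inputs <- config$inputs
    if (is.character(inputs$peak_manifest)) {
      inputs$peak_manifest <- utils::read.delim(inputs$peak_manifest,
                                                stringsAsFactors = FALSE)
    }
  }

  genome <- pipeline_stage("read-annotation", log, read_gff3(inputs$gff))
  peaks <- pipeline_stage("read-peaks", log, {
    mf <- inputs$peak_manifest
    do.call(rbind, lapply(seq_len(nrow(mf)), function(i) {
      b <- read_bed(mf$path[i], genome)
      if (!nrow(b)) return(NULL)
      data.frame(caste = mf$caste[i], replicate = mf$replicate[i], b,
                 stringsAsFactors = FALSE)
    }))
  })
  samples <- unique(inputs$peak_manifest[, c("caste", "replicate")])

  classified <- pipeline_stage("classify-peaks", log, {
    cons <- build_consensus(peaks, samples = samples)
    cons <- classify_peaks(cons, fc_threshold = config$fc_threshold,
                           alpha = config$alpha)
    annotate_peaks(cons, genome, config$promoter_upstream,
                   config$promoter_downstream)
  })
  pk <- classified$peaks
  utils::write.table(pk, file.path(outdir, "classified_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed_out <- pk
  bed_out$name <- paste(pk$peak_id, pk$class, pk$feature, sep = "|")
  bed_out$score <- ifelse(is.na(pk$fold_change), 0, pk$fold_change)
  write_bed(bed_out, file.path(outdir, "classified_peaks.bed"))

  dist_tests <- pipeline_stage("distribution-test", log, {
    run_test <- function(sel_A, sel_B) {
      tryCatch({
        r <- distribution_test(pk$feature[sel_A], pk$feature[sel_B])
        list(chi_squared = r$statistic, df = r$df, p_value = r$p_value,
             table = r$table)
      }, error = function(e) list(chi_squared = NA_real_, df = NA_integer_,
                                  p_value = NA_real_, error = conditionMessage(e)))
    }
    list(unique = run_test(pk$class == "unique_A", pk$class == "unique_B"),
         differential = run_test(pk$class == "differential_up_A",
                                 pk$class == "differential_up_B"))
  })

  counts <- pipeline_stage("read-counts", log, read_counts(inputs$counts))
  groups <- factor(sub("_rep.*$", "", colnames(counts)))
  groups <- factor(groups, levels = sort(levels(groups)))
  de <- pipeline_stage("diffexpr", log, {
    lens <- NULL
    if (nrow(genome$exons)) {
      ex_len <- tapply(genome$exons$end - genome$exons$start,
                       genome$exons$gene_id, sum)
      lens <- as.numeric(ex_len[rownames(counts)])
    }
    nb_diffexpr(counts, groups, gene_lengths = lens,
                prior_df = config$prior_df,
                deg_threshold = config$deg_threshold)
  })
  utils::write.table(de, file.path(outdir, "diffexpr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  integ <- pipeline_stage("integrate", log, {
    links <- link_peaks_to_genes(classified, genome,
                                 config$promoter_upstream,
                                 config$promoter_downstream)
    diff_ids <- pk$peak_id[grepl("^differential", pk$class)]
    dpg <- sort(unique(links$gene_id[links$peak_id %in% diff_ids]))
    deg <- sort(de$gene_id[de$deg])
    ov <- overlap_sets(deg, dpg)
    corr <- tryCatch(signal_expression_correlation(classified, links, de),
                     error = function(e) NULL)
    list(links = links, dpg = dpg, deg = deg, overlap = ov, corr = corr)
  })
  utils::write.table(integ$links, file.path(outdir, "peak_gene_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  profile <- pipeline_stage("tss-metaprofile", log, {
    if (is.null(inputs$coverage)) NULL else {
      sig <- read_bedgraph(inputs$coverage[[length(inputs$coverage)]])
      tss_metaprofile(sig, genome, flank = 2000,
                      bin_size = 50)
    }
  })
  if (!is.null(profile)) {
    utils::write.table(profile, file.path(outdir, "tss_metaprofile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  qpcr_res <- pipeline_stage("qpcr", log, {
    if (is.null(inputs$ct)) NULL else {
      ct <- read_ct_table(inputs$ct)
      targets <- setdiff(unique(ct$gene), "GAPDH")
      lapply(stats::setNames(targets, targets), function(g) {
        rq <- delta_delta_ct(ct, g, "GAPDH", config$qpcr_control)
        tt <- group_ttest(rq)
        list(summary = rq$summary, t = tt$t, p_value = tt$p_value)
      })
    }
  })

  report <- build_report(config, pk, dist_tests, de, integ, profile, qpcr_res,
                         truth)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(format_report(report), file.path(outdir, "summary.txt"))
  invisible(list(report = report, classified = classified, de = de,
                 integration = integ, profile = profile, qpcr = qpcr_res,
                 genome = genome, truth = truth, outdir = outdir))
}

category_percentages <- function(feature) {
  lev <- c("promoter", "exon", "intron", "intergenic")
  tab <- table(factor(feature, levels = lev))
  n <- sum(tab)
  pct <- if (n) round(100 * as.numeric(tab) / n, 2) else rep(0, length(lev))
  as.list(stats::setNames(pct, lev))
}

build_report <- function(config, pk, dist_tests, de, integ, profile, qpcr_res,
                         truth) {
  cls <- table(factor(pk$class, levels = c("unique_A", "unique_B",
                                           "differential_up_A",
                                           "differential_up_B",
                                           "shared", "unresolved")))
  report <- list(
    comparison = "Q_vs_W",
    seed = config$seed,
    thresholds = list(fc = config$fc_threshold, alpha = config$alpha,
                      deg_p_adj = config$deg_threshold,
                      promoter_upstream = config$promoter_upstream,
                      promoter_downstream = config$promoter_downstream),
    peaks = c(list(n_consensus = nrow(pk)), as.list(cls)),
    unique_peak_categories = list(
      A = category_percentages(pk$feature[pk$class == "unique_A"]),
      B = category_percentages(pk$feature[pk$class == "unique_B"])),
    distribution_tests = dist_tests,
    expression = list(n_genes = nrow(de), n_deg = sum(de$deg),
                      n_deg_up = sum(de$deg & de$log2_fold_change > 0),
                      n_deg_down = sum(de$deg & de$log2_fold_change < 0)),
    integration = list(
      n_dpg = length(integ$dpg),
      n_deg = length(integ$deg),
      deg_dpg_overlap = integ$overlap$intersection,
      jaccard = integ$overlap$jaccard,
      correlation = if (!is.null(integ$corr)) list(
        all = list(rho = integ$corr$all$rho, n = integ$corr$all$n,
                   p_value = integ$corr$all$p_value),
        deg_only = if (!is.null(integ$corr$deg_only)) list(
          rho = integ$corr$deg_only$rho, n = integ$corr$deg_only$n,
          p_value = integ$corr$deg_only$p_value))),
    tss_metaprofile = if (!is.null(profile)) list(
      argmax_offset = profile$offset[which.max(profile$mean_signal)],
      n_genes = max(profile$n_genes)),
    qpcr = qpcr_res
  )
  if (!is.null(truth)) {
    tp <- truth$peaks
    report$truth_recovery <- list(
      planted_unique_A = sum(tp$class == "unique_A"),
      planted_unique_B = sum(tp$class == "unique_B"),
      planted_differential = sum(grepl("^differential", tp$class)),
      planted_de_genes = sum(truth$genes$de))
  }
  # internal consistency: every reported count must equal its table
  stopifnot(report$peaks$n_consensus == nrow(pk),
            report$peaks$unique_A == sum(pk$class == "unique_A"),
            report$peaks$unique_B == sum(pk$class == "unique_B"),
            report$expression$n_deg == sum(de$deg),
            report$integration$n_dpg == length(integ$dpg),
            report$integration$deg_dpg_overlap ==
              length(intersect(integ$deg, integ$dpg)))
  for (caste in c("A", "B")) {
    pc <- unlist(report$unique_peak_categories[[caste]])
    if (sum(pc) > 0 && abs(sum(pc) - 100) > 0.1) {
      stopf("category percentages for caste %s do not sum to 100", caste)
    }
  }
  report
}

format_report <- function(r) {
  c(sprintf("casteChIP summary report (%s, seed %d)", r$comparison, r$seed),
    "",
    sprintf("Consensus peaks: %d", r$peaks$n_consensus),
    sprintf("  unique to Q (A): %d   unique to W (B): %d",
            r$peaks$unique_A, r$peaks$unique_B),
    sprintf("  differential up in Q: %d   up in W: %d   shared: %d   unresolved: %d",
            r$peaks$differential_up_A, r$peaks$differential_up_B,
            r$peaks$shared, r$peaks$unresolved),
    sprintf("Unique-peak distribution chi-squared: %s (p = %s)",
            fmt_num(r$distribution_tests$unique$chi_squared, 6),
            fmt_num(r$distribution_tests$unique$p_value, 4)),
    sprintf("DEGs (p_adj <= %s): %d (%d up, %d down)",
            fmt_num(r$thresholds$deg_p_adj, 3), r$expression$n_deg,
            r$expression$n_deg_up, r$expression$n_deg_down),
    sprintf("DPGs: %d   DEG-DPG overlap: %d", r$integration$n_dpg,
            r$integration$deg_dpg_overlap),
    if (!is.null(r$integration$correlation)) {
      sprintf("Signal-expression Spearman rho: %s (n = %d, p = %s)",
              fmt_num(r$integration$correlation$all$rho, 4),
              r$integration$correlation$all$n,
              fmt_num(r$integration$correlation$all$p_value, 4))
    },
    if (!is.null(r$tss_metaprofile)) {
      sprintf("TSS metaprofile argmax offset: %d bp", r$tss_metaprofile$argmax_offset)
    })
}
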