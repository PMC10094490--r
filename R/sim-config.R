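#' Simulation configuration
#'
#' Parameters of the synthetic study: a single-chromosome genome, two
#' castes (A = queen-like, B = worker-like) times `n_replicates` replicate
#' peak sets with planted caste-unique and fold-change differential peaks,
#' an NB count matrix with planted differentially expressed genes, and a
#' qPCR Ct table. Defaults emulate the 4th-instar caste contrast the
#' analysis is built around: more worker-unique peaks sitting in promoters
#' (`frac_unique_in_promoter_casteB`), queen-unique peaks in introns
#' (`frac_unique_in_intron_casteA`), three replicates per caste, and a
#' moderate NB dispersion. No public peak-width or depth conventions exist
#' for this design, so those defaults are the package's own (see the
#' methods vignette).
#'
#' @param seed integer RNG seed; every simulator output is a pure function
#'   of the configuration including this seed.
#' @param chrom_length chromosome length in bases. The default (5e6) holds
#'   `n_genes` genes of length 2-10 kb with realistic intergenic space.
#' @param n_genes number of non-overlapping genes.
#' @param n_background_peaks peaks present in all replicates of both
#'   castes with equal means.
#' @param n_unique_peaks_per_caste planted caste-unique peaks per caste.
#' @param n_differential_peaks planted fold-change differential peaks
#'   (present in both castes).
#' @param planted_log2fc magnitude scale of differential-peak log2 fold
#'   changes (per-peak magnitudes vary by +/-20% around it).
#' @param peak_mean_count NB mean read count per peak and replicate.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param n_replicates replicates per caste.
#' @param frac_unique_in_promoter_casteB fraction of caste-B unique peaks
#'   planted in promoter windows.
#' @param frac_unique_in_intron_casteA fraction of caste-A unique peaks
#'   planted in introns.
#' @param frac_differential_in_promoter fraction of differential peaks
#'   planted in promoter windows (the peaks that can drive linked
#'   expression changes).
#' @param n_de_genes planted differentially expressed genes (chosen among
#'   genes not owning a planted promoter differential peak).
#' @param de_log2fc expression log2 fold change of planted DE genes; also
#'   the scale of the correlated effects on peak-linked genes.
#' @param rna_mean_count typical NB mean expression count.
#' @param signal_expression_rho target Spearman correlation, in [-1, 1],
#'   between measured promoter-peak log2FC and expression log2FC over
#'   peak-linked genes.
#' @param dropout_prob probability that a planted unique peak is missed in
#'   one replicate of its own caste (exists to probe the strictness of the
#'   all-replicates rule).
#' @param promoter_upstream,promoter_downstream promoter window used when
#'   planting peaks by feature category.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_length = 5e6,
                              n_genes = 500,
                              n_background_peaks = 400,
                              n_unique_peaks_per_caste = 60,
                              n_differential_peaks = 80,
                              planted_log2fc = 2.0,
                              peak_mean_count = 100,
                              nb_dispersion = 0.05,
                              n_replicates = 3,
                              frac_unique_in_promoter_casteB = 0.6,
                              frac_unique_in_intron_casteA = 0.6,
                              frac_differential_in_promoter = 0.5,
                              n_de_genes = 100,
                              de_log2fc = 1.5,
                              rna_mean_count = 200,
                              signal_expression_rho = 0.3,
                              dropout_prob = 0.0,
                              promoter_upstream = 2000,
                              promoter_downstream = 200) {
  cfg <- list(seed = as.integer(seed), chrom_length = chrom_length,
              n_genes = n_genes, n_background_peaks = n_background_peaks,
              n_unique_peaks_per_caste = n_unique_peaks_per_caste,
              n_differential_peaks = n_differential_peaks,
              planted_log2fc = planted_log2fc,
              peak_mean_count = peak_mean_count,
              nb_dispersion = nb_dispersion, n_replicates = n_replicates,
              frac_unique_in_promoter_casteB = frac_unique_in_promoter_casteB,
              frac_unique_in_intron_casteA = frac_unique_in_intron_casteA,
              frac_differential_in_promoter = frac_differential_in_promoter,
              n_de_genes = n_de_genes, de_log2fc = de_log2fc,
              rna_mean_count = rna_mean_count,
              signal_expression_rho = signal_expression_rho,
              dropout_prob = dropout_prob,
              promoter_upstream = promoter_upstream,
              promoter_downstream = promoter_downstream)
  check_number(cfg$chrom_length, "chrom_length", min = 1)
  for (nm in c("n_genes", "n_background_peaks", "n_unique_peaks_per_caste",
               "n_differential_peaks", "n_de_genes")) {
    check_number(cfg[[nm]], nm, min = 0)
  }
  check_number(cfg$n_replicates, "n_replicates", min = 1)
  for (nm in c("frac_unique_in_promoter_casteB", "frac_unique_in_intron_casteA",
               "frac_differential_in_promoter", "dropout_prob")) {
    check_number(cfg[[nm]], nm, min = 0, max = 1)
  }
  check_number(cfg$nb_dispersion, "nb_dispersion", min = 0)
  check_number(cfg$peak_mean_count, "peak_mean_count", min = 0)
  check_number(cfg$rna_mean_count, "rna_mean_count", min = 0)
  check_number(cfg$signal_expression_rho, "signal_expression_rho",
               min = -1, max = 1)
  check_number(cfg$promoter_upstream, "promoter_upstream", min = 0)
  check_number(cfg$promoter_downstream, "promoter_downstream", min = 0)
  # genes are 2-10 kb plus a 1-base spacer each; fail early when they
  # cannot all fit
  if (cfg$n_genes * 2001 > cfg$chrom_length) {
    stopf("genome too dense: %d genes of >= 2 kb cannot fit in %g bases",
          cfg$n_genes, cfg$chrom_length)
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, fmt_num(x[[nm]], 8)))
  invisible(x)
}
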