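# Unique / differential classification of consensus peaks, following the
# replicate-consistency rule: a peak is unique to a caste when it is
# detected in every replicate of that caste and in no replicate of the
# other; a differential peak needs p below alpha and fold change above the
# threshold between castes. Unique classification runs first, so peaks
# absent from one caste are never also counted as differential.

#' Classify a peak as caste-unique from replicate presence flags
#'
#' @param presence_A,presence_B logical vectors (one peak) or matrices
#'   (peaks x replicates) of presence flags per caste.
#' @return `"unique_A"`, `"unique_B"`, or `NA_character_` per peak.
#' @export
classify_unique <- function(presence_A, presence_B) {
  if (is.null(dim(presence_A))) presence_A <- matrix(presence_A, nrow = 1)
  if (is.null(dim(presence_B))) presence_B <- matrix(presence_B, nrow = 1)
  all_A <- rowSums(presence_A) == ncol(presence_A)
  all_B <- rowSums(presence_B) == ncol(presence_B)
  none_A <- rowSums(presence_A) == 0
  none_B <- rowSums(presence_B) == 0
  ifelse(all_A & none_B, "unique_A",
         ifelse(all_B & none_A, "unique_B", NA_character_))
}

#' Library-size normalization factors for replicate peak signal
#'
#' Each replicate's total peak signal is scaled to the median library:
#' `factor_j = total_j / median(totals)`; normalized signal is
#' `signal / factor`. Zero-total replicates get factor 1 (nothing to scale).
#'
#' @param signal numeric matrix, peaks x samples.
#' @return named numeric vector of positive per-sample factors.
#' @export
peak_size_factors <- function(signal) {
  totals <- colSums(signal)
  med <- stats::median(totals[totals > 0])
  f <- totals / med
  f[!is.finite(f) | f <= 0] <- 1
  f
}

#' Two-caste differential test for one peak
#'
#' Welch's two-sided t-test on `log2(normalized signal + pseudo)`, with the
#' linear fold change computed as `(mean_A + pseudo) / (mean_B + pseudo)`.
#' The peak is called differential when `p < alpha` and
#' `max(fc, 1/fc) > fc_threshold`, with direction taken from the sign of
#' the mean difference. Castes with fewer than two nonzero replicates make
#' the peak `"unresolved"` rather than erroring.
#'
#' @param sig_A,sig_B numeric vectors of normalized per-replicate signal.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @param pseudo pseudo-count on the normalized scale (default 1).
#' @return list with `fold_change` (A over B), `log2_fold_change`,
#'   `p_value`, and `class` (`"differential_up_A"`, `"differential_up_B"`,
#'   `"shared"`, or `"unresolved"`).
#' @export
test_differential <- function(sig_A, sig_B, fc_threshold = 2, alpha = 0.05,
                              pseudo = 1) {
  fc <- (mean(sig_A) + pseudo) / (mean(sig_B) + pseudo)
  lfc <- log2(fc)
  if (sum(sig_A > 0) < 2L || sum(sig_B > 0) < 2L) {
    return(list(fold_change = fc, log2_fold_change = lfc,
                p_value = NA_real_, class = "unresolved"))
  }
  la <- log2(sig_A + pseudo)
  lb <- log2(sig_B + pseudo)
  p <- welch_p(la, lb)
  cls <- "shared"
  if (!is.na(p) && p < alpha && max(fc, 1 / fc) > fc_threshold) {
    cls <- if (mean(sig_A) > mean(sig_B)) "differential_up_A" else "differential_up_B"
  }
  list(fold_change = fc, log2_fold_change = lfc, p_value = p, class = cls)
}

# Welch two-sided p; constant-data degenerate cases resolved by comparing
# means instead of erroring.
welch_p <- function(a, b, tol = 1e-12) {
  if (stats::var(a) < tol && stats::var(b) < tol) {
    return(if (abs(mean(a) - mean(b)) < tol) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Classify all consensus peaks as unique, differential, shared or unresolved
#'
#' Applies, in order: (1) the strict all-replicates unique rule; (2) the
#' Welch fold-change test on library-normalized signal for the remaining
#' peaks. Every peak receives exactly one class.
#'
#' @param consensus a [build_consensus()] object with exactly two castes.
#' @param fc_threshold,alpha,pseudo see [test_differential()].
#' @param normalize apply [peak_size_factors()] before testing
#'   (default `TRUE`).
#' @return the `consensus_peaks` object with `peaks` gaining `class`,
#'   `fold_change`, `log2_fold_change` and `p_value` columns, and an
#'   added `normalized` signal matrix. Fold changes are caste A over
#'   caste B, castes in sorted label order.
#' @export
classify_peaks <- function(consensus, fc_threshold = 2, alpha = 0.05,
                           pseudo = 1, normalize = TRUE) {
  castes <- sort(unique(consensus$samples$caste))
  if (length(castes) != 2L) stopf("classification needs exactly 2 castes, got %d",
                                  length(castes))
  iA <- which(consensus$samples$caste == castes[1])
  iB <- which(consensus$samples$caste == castes[2])
  sig <- consensus$signal
  if (normalize && nrow(sig)) {
    sig <- sweep(sig, 2, peak_size_factors(sig), "/")
  }
  np <- nrow(consensus$peaks)
  class <- character(np)
  fc <- p <- rep(NA_real_, np)
  uq <- classify_unique(consensus$presence[, iA, drop = FALSE],
                        consensus$presence[, iB, drop = FALSE])
  for (i in seq_len(np)) {
    if (!is.na(uq[i])) {
      class[i] <- uq[i]
      fc[i] <- (mean(sig[i, iA]) + pseudo) / (mean(sig[i, iB]) + pseudo)
      next
    }
    r <- test_differential(sig[i, iA], sig[i, iB], fc_threshold, alpha, pseudo)
    class[i] <- r$class
    fc[i] <- r$fold_change
    p[i] <- r$p_value
  }
  consensus$peaks$class <- class
  consensus$peaks$fold_change <- fc
  consensus$peaks$log2_fold_change <- log2(fc)
  consensus$peaks$p_value <- p
  consensus$normalized <- sig
  consensus$castes <- castes
  consensus
}

#' Annotate peaks with their genomic feature category
#'
#' Each peak is assigned the category of its midpoint
#' (`floor((start + end) / 2)`), via [classify_position()]. Midpoint
#' assignment is deterministic and order-independent.
#'
#' @param x a `consensus_peaks` object or a data.frame with `chrom`,
#'   `start`, `end`.
#' @param genome a [genome_annotation()].
#' @param upstream,downstream promoter window extent.
#' @return the input with added `feature` (and `gene_id`, `dist_tss`)
#'   columns.
#' @export
annotate_peaks <- function(x, genome, upstream = 2000, downstream = 200) {
  df <- if (inherits(x, "consensus_peaks")) x$peaks else x
  mid <- (df$start + df$end) %/% 2L
  cl <- classify_position(data.frame(chrom = df$chrom, pos = mid,
                                     stringsAsFactors = FALSE),
                          genome, upstream, downstream)
  df$feature <- cl$category
  df$gene_id <- cl$gene_id
  df$dist_tss <- cl$dist_tss
  if (inherits(x, "consensus_peaks")) {
    x$peaks <- df
    x
  } else {
    df
  }
}
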