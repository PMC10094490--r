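# Self-contained negative-binomial differential expression: median-of-ratios
# size factors, moderated method-of-moments dispersion, a Wald test on the
# log2 fold change, step-up Benjamini-Hochberg FDR, and FPKM. The model is
# NB with variance mu + alpha * mu^2.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g(count_gj / geometric_mean_g)`, where the geometric
#' mean is over samples and genes with any zero count are excluded from the
#' median. Factors are reported as computed (no rescaling to unit product).
#'
#' @param counts non-negative count matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    stopf(paste("no gene has nonzero counts in every sample;",
                "consider a pseudo-reference fallback (e.g. counts + 1)"))
  }
  geo <- exp(rowMeans(log(counts[usable, , drop = FALSE])))
  f <- apply(counts[usable, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
  if (any(f <= 0)) stopf("non-positive size factor; check the count matrix")
  f
}

#' Moderated method-of-moments NB dispersion estimates
#'
#' Per gene, within-group moments on the normalized scale give the raw
#' estimate `alpha_g = (s^2 - mean) / mean^2`, pooled across the two groups
#' weighted by degrees of freedom `n_k - 1` and floored. With only a few
#' replicates this estimate is very noisy, so by default it is shrunk
#' toward the across-gene median with `prior_df` pseudo-degrees of freedom:
#' `alpha~ = (df_g * alpha_g + prior_df * median(alpha)) / (df_g + prior_df)`.
#' `prior_df = 0` gives the raw per-gene estimator.
#'
#' @param counts count matrix, genes x samples.
#' @param factors per-sample size factors, see [size_factors()].
#' @param groups factor or character vector of group labels per sample.
#' @param prior_df moderation strength in pseudo-df (default 20).
#' @param floor smallest admissible dispersion (default 1e-8).
#' @return object of class `dispersion_estimate`: list with `alpha`
#'   (moderated, used downstream), `raw`, `center`, `df` (per-gene moment
#'   df), and `total_df = df + prior_df` (reference df for the Wald test).
#' @export
estimate_dispersion <- function(counts, factors, groups, prior_df = 20,
                                floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  tab <- table(groups)
  if (any(tab < 2)) {
    stopf("each group needs >= 2 samples to estimate dispersion (got %s)",
          paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
  }
  norm <- sweep(counts, 2, factors, "/")
  num <- 0
  den <- 0
  for (lev in levels(groups)) {
    m <- norm[, groups == lev, drop = FALSE]
    mu <- rowMeans(m)
    s2 <- apply(m, 1, stats::var)
    w <- ncol(m) - 1L
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    num <- num + w * a
    den <- den + w
  }
  raw <- pmax(floor, num / den)
  center <- stats::median(raw)
  alpha <- if (prior_df > 0) {
    pmax(floor, (den * raw + prior_df * center) / (den + prior_df))
  } else {
    raw
  }
  structure(list(alpha = alpha, raw = raw, center = center,
                 df = den, total_df = den + prior_df, prior_df = prior_df,
                 floor = floor),
            class = "dispersion_estimate")
}

#' NB Wald test for two-group differential expression
#'
#' Per gene, the normalized group means `m1`, `m2` give
#' `log2FC = log2(m1 / m2)` (a pseudo-count of 0.5 per sample on the
#' normalized scale is added to both groups when either group mean is 0,
#' keeping the fold change finite; affected genes are flagged). The
#' standard error of each group's log2 mean comes from the delta method,
#' `SE_i = sqrt((m_i + alpha * m_i^2) / (n_i * m_i^2)) / ln 2`, and the
#' Wald statistic `z = log2FC / sqrt(SE1^2 + SE2^2)` is referenced against
#' a Student t distribution with the dispersion estimate's total degrees
#' of freedom (moment df plus moderation prior df), a small-sample
#' calibration of the usual normal reference. BH-adjusted p-values and the
#' DEG flag (`p_adj <= deg_threshold`) are included.
#'
#' @param counts count matrix, genes x samples.
#' @param factors per-sample size factors.
#' @param dispersion a [estimate_dispersion()] object (or a bare numeric
#'   vector of per-gene dispersions, in which case a normal reference is
#'   used).
#' @param groups two-level factor; the first level is the numerator of the
#'   fold change.
#' @param deg_threshold adjusted-p cutoff defining DEGs (default 0.05).
#' @return data.frame with columns `gene_id`, `baseMean`,
#'   `log2_fold_change`, `se`, `stat`, `p_value`, `p_adj`, `deg`,
#'   `pseudo_applied`.
#' @export
nb_wald_test <- function(counts, factors, dispersion, groups,
                         deg_threshold = 0.05) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups required")
  tab <- table(groups)
  if (any(tab < 2)) stopf("each group needs >= 2 samples")
  if (inherits(dispersion, "dispersion_estimate")) {
    alpha <- dispersion$alpha
    ref_df <- dispersion$total_df
  } else {
    alpha <- dispersion
    ref_df <- Inf
  }
  norm <- sweep(counts, 2, factors, "/")
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  pseudo <- m1 == 0 | m2 == 0
  m1p <- ifelse(pseudo, m1 + 0.5, m1)
  m2p <- ifelse(pseudo, m2 + 0.5, m2)
  lfc <- log2(m1p / m2p)
  se1 <- sqrt((m1p + alpha * m1p^2) / (n1 * m1p^2)) / log(2)
  se2 <- sqrt((m2p + alpha * m2p^2) / (n2 * m2p^2)) / log(2)
  se <- sqrt(se1^2 + se2^2)
  z <- lfc / se
  p <- if (is.finite(ref_df)) 2 * stats::pt(-abs(z), df = ref_df)
       else 2 * stats::pnorm(-abs(z))
  padj <- bh_adjust(p)
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             baseMean = rowMeans(norm),
             log2_fold_change = lfc, se = se, stat = z,
             p_value = p, p_adj = padj,
             deg = !is.na(padj) & padj <= deg_threshold,
             pseudo_applied = pseudo,
             stringsAsFactors = FALSE)
}

#' Step-up Benjamini-Hochberg adjustment
#'
#' Standard BH with monotonicity enforcement; input order is preserved and
#' `NA` entries stay `NA` without entering the adjustment.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (!n) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * n / seq(n, 1)))
  out[ok[o]] <- adj
  out
}

#' FPKM expression values
#'
#' `FPKM_gj = count_gj * 1e9 / (length_g * total_j)`.
#'
#' @param counts count matrix, genes x samples.
#' @param gene_lengths per-gene transcript lengths in bases.
#' @param totals per-sample totals of mapped reads; defaults to column
#'   sums of `counts`.
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) {
    stopf("gene_lengths must have one entry per gene")
  }
  if (any(gene_lengths <= 0) || any(totals <= 0)) {
    stopf("gene lengths and totals must be positive")
  }
  sweep(counts / gene_lengths, 2, totals, "/") * 1e9
}

#' One-call NB differential expression
#'
#' Convenience wrapper chaining [size_factors()], [estimate_dispersion()]
#' and [nb_wald_test()], optionally appending FPKM means per group.
#'
#' @param counts count matrix, genes x samples.
#' @param groups two-level factor of sample groups.
#' @param gene_lengths optional per-gene lengths for FPKM columns.
#' @param prior_df,deg_threshold see [estimate_dispersion()] and
#'   [nb_wald_test()].
#' @return the [nb_wald_test()] data.frame (plus per-group mean FPKM
#'   columns when lengths are given).
#' @export
nb_diffexpr <- function(counts, groups, gene_lengths = NULL, prior_df = 20,
                        deg_threshold = 0.05) {
  groups <- as.factor(groups)
  f <- size_factors(counts)
  disp <- estimate_dispersion(counts, f, groups, prior_df = prior_df)
  res <- nb_wald_test(counts, f, disp, groups, deg_threshold = deg_threshold)
  if (!is.null(gene_lengths)) {
    fp <- fpkm(counts, gene_lengths)
    for (lev in levels(groups)) {
      res[[paste0("fpkm_", lev)]] <- rowMeans(fp[, groups == lev, drop = FALSE])
    }
  }
  res
}
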