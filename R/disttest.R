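#' Chi-squared test for caste differences in peak-position distributions
#'
#' Builds a 2 x k contingency table of feature categories (promoter,
#' exon, intron by default; intergenic peaks are excluded before
#' tabulation, since the three gene-linked categories are reported as an
#' exclusive three-way split) and applies Pearson's chi-squared test of
#' independence without continuity correction, with expected counts from
#' the table margins and `df = (rows - 1) * (cols - 1)`.
#'
#' @param x feature categories for the first caste's peaks (character
#'   vector), or a complete contingency table (matrix, rows = castes)
#'   in which case `y` and `categories` are ignored.
#' @param y feature categories for the second caste's peaks.
#' @param categories categories to tabulate; others are dropped.
#' @return object of class `distribution_test`: list with `table`,
#'   `statistic`, `df`, `p_value`, `expected`.
#' @export
distribution_test <- function(x, y = NULL,
                              categories = c("promoter", "exon", "intron")) {
  if (is.matrix(x)) {
    tab <- x
  } else {
    if (is.null(y)) stopf("need categories for both castes, or a matrix")
    tab <- rbind(
      A = table(factor(x[x %in% categories], levels = categories)),
      B = table(factor(y[y %in% categories], levels = categories))
    )
  }
  tab <- as.matrix(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) {
    stopf("zero row margin for '%s'", paste(rownames(tab)[rs == 0] %||%
                                              which(rs == 0), collapse = ", "))
  }
  if (any(cs == 0)) {
    stopf("zero column margin for '%s'", paste(colnames(tab)[cs == 0] %||%
                                                 which(cs == 0), collapse = ", "))
  }
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(table = tab, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected),
            class = "distribution_test")
}

#' @export
print.distribution_test <- function(x, ...) {
  cat(sprintf("chi-squared test of independence: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}
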