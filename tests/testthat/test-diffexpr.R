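# Negative-binomial differential expression machinery.

random_counts <- function(n_genes, n_samples, seed, mu = 100, alpha = 0.05) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / alpha),
              n_genes, n_samples)
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%d", seq_len(n_samples))
  m
}

test_that("size factors are 1 for identical samples and scale with depth", {
  m <- random_counts(40, 1, 1) %*% t(rep(1, 3))
  colnames(m) <- c("a", "b", "c")
  expect_equal(unname(size_factors(m)), rep(1, 3))

  m2 <- cbind(A = m[, 1], B = 2 * m[, 1])
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2)
})

test_that("size factors equal a step-by-step hand implementation", {
  m <- random_counts(50, 4, 2, mu = 200) + 1  # all-positive
  f <- size_factors(m)
  # independent re-derivation, spelled out
  geo <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  hand <- vapply(seq_len(ncol(m)), function(j) {
    ratios <- m[, j] / geo
    stats::median(ratios)
  }, 0)
  expect_equal(unname(f), hand, tolerance = 1e-12)
})

test_that("size factors agree with the median-of-ratios reference implementation", {
  skip_if_not_installed("DESeq2")
  m <- random_counts(51, 4, 3, mu = 150) + 1  # odd gene count, all positive
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("all-zero-overlap matrices error with a pseudo-reference hint", {
  m <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(m), "pseudo-reference")
})

test_that("dispersion estimation recovers planted values and floors constants", {
  groups <- rep(c("Q", "W"), each = 3)
  m <- random_counts(2000, 6, 4, mu = 100, alpha = 0.05)
  d <- estimate_dispersion(m, rep(1, 6), groups)
  expect_gt(median(d$raw), 0.03)
  expect_lt(median(d$raw), 0.07)
  expect_gt(median(d$alpha), 0.03)
  expect_lt(median(d$alpha), 0.07)

  pois <- random_counts(2000, 6, 5, mu = 100, alpha = 1e-12)
  dp <- estimate_dispersion(pois, rep(1, 6), groups, prior_df = 0)
  expect_lte(median(dp$alpha), 0.01)

  const <- matrix(100, 10, 6, dimnames = list(sprintf("g%d", 1:10), NULL))
  dc <- estimate_dispersion(const, rep(1, 6), groups, prior_df = 0)
  expect_equal(unname(dc$alpha), rep(1e-8, 10))

  expect_error(estimate_dispersion(m[, 1:3], rep(1, 3), c("Q", "Q", "W")),
               ">= 2 samples")
})

test_that("Wald log2 fold changes are exact for exact mean ratios", {
  m <- cbind(matrix(400, 5, 3), matrix(100, 5, 3))
  rownames(m) <- sprintf("g%d", 1:5)
  groups <- factor(rep(c("Q", "W"), each = 3), levels = c("Q", "W"))
  res <- nb_wald_test(m, rep(1, 6), rep(0.05, 5), groups)
  expect_equal(res$log2_fold_change, rep(2, 5))
  # identical groups: z = 0, p = 1
  m0 <- cbind(matrix(100, 5, 3), matrix(100, 5, 3))
  rownames(m0) <- sprintf("g%d", 1:5)
  res0 <- nb_wald_test(m0, rep(1, 6), rep(0.05, 5), groups)
  expect_equal(res0$stat, rep(0, 5))
  expect_equal(res0$p_value, rep(1, 5))
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  m <- random_counts(300, 6, 6, mu = 150)
  groups <- factor(rep(c("Q", "W"), each = 3), levels = c("Q", "W"))
  f <- size_factors(m)
  d <- estimate_dispersion(m, f, groups)
  r1 <- nb_wald_test(m, f, d, groups)
  r2 <- nb_wald_test(m, f, d, factor(groups, levels = c("W", "Q")))
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("zero group means get the pseudo-count and stay finite", {
  m <- cbind(matrix(0, 2, 3), matrix(64, 2, 3))
  rownames(m) <- c("g1", "g2")
  groups <- factor(rep(c("Q", "W"), each = 3))
  res <- nb_wald_test(m, rep(1, 6), rep(0.05, 2), groups)
  expect_true(all(is.finite(res$log2_fold_change)))
  expect_true(all(res$pseudo_applied))
  expect_equal(res$log2_fold_change, rep(log2(0.5 / 64.5), 2))
})

test_that("BH adjustment matches the worked example and its bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p & adj <= 1))
    expect_equal(adj, p.adjust(p, "BH"))
  }
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})

test_that("FPKM formula, zero counts and scale invariance", {
  m <- matrix(c(100, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(m, c(1000, 1000), totals = 1e7)
  expect_equal(unname(f[, 1]), c(10, 0))
  m2 <- random_counts(20, 2, 8)
  expect_equal(fpkm(2 * m2, rep(500, 20), totals = 2 * colSums(m2)),
               fpkm(m2, rep(500, 20)))
})
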