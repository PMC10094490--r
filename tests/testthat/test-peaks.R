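# Consensus construction and unique/differential classification.

make_peaks <- function(...) {
  # rows of (caste, replicate, start, end, score)
  d <- do.call(rbind, lapply(list(...), function(r) {
    data.frame(caste = r[[1]], replicate = as.integer(r[[2]]),
               chrom = "chrT", start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), score = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
  d
}

full_samples <- data.frame(caste = rep(c("Q", "W"), each = 3),
                           replicate = rep(1:3, 2))

test_that("identical intervals across six replicates give one 6/6 consensus peak", {
  rows <- do.call(make_peaks, c(
    lapply(1:3, function(r) list("Q", r, 100, 1100, 50)),
    lapply(1:3, function(r) list("W", r, 100, 1100, 50))))
  cons <- build_consensus(rows)
  expect_equal(nrow(cons$peaks), 1)
  expect_true(all(cons$presence))
  expect_true(all(cons$signal == 50))
})

test_that("disjoint and book-ended intervals stay separate; overlaps merge", {
  cons <- build_consensus(make_peaks(list("Q", 1, 0, 100, 1),
                                     list("Q", 2, 100, 200, 1),
                                     list("W", 1, 500, 700, 1),
                                     list("W", 2, 650, 900, 1)),
                          samples = full_samples)
  expect_equal(cons$peaks$start, c(0, 100, 500))
  expect_equal(cons$peaks$end, c(100, 200, 900))
})

test_that("two replicate peaks overlapping one consensus interval sum their scores", {
  cons <- build_consensus(make_peaks(list("Q", 1, 0, 300, 10),
                                     list("Q", 1, 250, 500, 7),
                                     list("Q", 2, 100, 400, 5)),
                          samples = full_samples)
  expect_equal(nrow(cons$peaks), 1)
  expect_equal(unname(cons$signal[1, "Q_rep1"]), 17)
  expect_equal(unname(cons$signal[1, "Q_rep2"]), 5)
  expect_equal(unname(cons$signal[1, "W_rep1"]), 0)
})

test_that("empty input yields an empty consensus, not an error", {
  cons <- build_consensus(make_peaks(list("Q", 1, 0, 10, 1))[0, ],
                          samples = full_samples)
  expect_equal(nrow(cons$peaks), 0)
})

test_that("consensus merging equals a connected-components oracle on random instances", {
  set.seed(99)
  for (case in 1:30) {
    n <- sample(5:120, 1)
    start <- sample.int(20000, n)
    width <- sample(50:800, n, replace = TRUE)
    d <- data.frame(caste = sample(c("Q", "W"), n, TRUE),
                    replicate = sample(1:3, n, TRUE), chrom = "chrT",
                    start = start, end = start + width, score = 1,
                    stringsAsFactors = FALSE)
    cons <- build_consensus(d, samples = full_samples)
    # oracle: graph whose edges are pairwise >= 1 bp overlaps; components
    adj <- outer(seq_len(n), seq_len(n), function(i, j) {
      d$start[i] < d$end[j] & d$start[j] < d$end[i]
    })
    comp <- seq_len(n)
    repeat {
      new_comp <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 1)
      if (all(new_comp == comp)) break
      comp <- new_comp
    }
    oracle <- unique(t(vapply(split(seq_len(n), comp), function(idx) {
      c(min(d$start[idx]), max(d$end[idx]))
    }, c(0, 0))))
    oracle <- oracle[order(oracle[, 1]), , drop = FALSE]
    expect_equal(cons$peaks$start, unname(oracle[, 1]))
    expect_equal(cons$peaks$end, unname(oracle[, 2]))
  }
})

test_that("unique classification matches the truth table over all 64 presence patterns", {
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  pa <- as.matrix(pat[, 1:3])
  pb <- as.matrix(pat[, 4:6])
  got <- classify_unique(pa, pb)
  for (i in seq_len(64)) {
    expected <- if (all(pa[i, ]) && !any(pb[i, ])) "unique_A"
    else if (all(pb[i, ]) && !any(pa[i, ])) "unique_B"
    else NA_character_
    expect_identical(got[i], expected)
  }
})

test_that("the unique rule is strict: 2/3 own replicates is not unique", {
  expect_true(is.na(classify_unique(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE))))
  expect_equal(classify_unique(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE)),
               "unique_A")
})

test_that("differential test reproduces an independent Welch computation", {
  a <- c(400, 410, 390); b <- c(100, 95, 105)
  got <- test_differential(a, b, pseudo = 1)
  # textbook Welch on log2(x + 1), written out from the formulas
  la <- log2(a + 1); lb <- log2(b + 1)
  se2 <- var(la) / 3 + var(lb) / 3
  tstat <- (mean(la) - mean(lb)) / sqrt(se2)
  df <- se2^2 / ((var(la) / 3)^2 / 2 + (var(lb) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(tstat), df)
  fc_hand <- (mean(a) + 1) / (mean(b) + 1)
  expect_equal(got$p_value, p_hand, tolerance = 1e-10)
  expect_equal(got$fold_change, fc_hand, tolerance = 1e-12)
  expect_equal(got$class, "differential_up_A")
})

test_that("differential calls need both thresholds", {
  expect_equal(test_differential(c(100, 100, 100), c(100, 100, 100))$class,
               "shared")
  # significant but under the fold threshold
  r <- test_differential(c(150, 152, 148), c(100, 101, 99))
  expect_lt(r$p_value, 0.05)
  expect_equal(r$class, "shared")
  # over the fold threshold but not significant
  r2 <- test_differential(c(400, 60, 260), c(80, 90, 100))
  expect_gt(r2$p_value, 0.05)
  expect_equal(r2$class, "shared")
  # both satisfied, direction B
  r3 <- test_differential(c(100, 95, 105), c(400, 410, 390))
  expect_equal(r3$class, "differential_up_B")
})

test_that("castes with under two detected replicates are unresolved", {
  r <- test_differential(c(100, 110, 90), c(0, 0, 5))
  expect_equal(r$class, "unresolved")
  expect_true(is.na(r$p_value))
})

test_that("swapping caste labels mirrors classes and inverts fold changes", {
  cfg <- small_config(seed = 12)
  sim <- simulate_peaks(cfg, simulate_genome(cfg))
  swapped <- sim$peaks
  swapped$caste <- ifelse(sim$peaks$caste == "Q", "W", "Q")
  c1 <- classify_peaks(build_consensus(sim$peaks))
  c2 <- classify_peaks(build_consensus(swapped))
  map <- c(unique_A = "unique_B", unique_B = "unique_A",
           differential_up_A = "differential_up_B",
           differential_up_B = "differential_up_A",
           shared = "shared", unresolved = "unresolved")
  expect_identical(unname(map[c1$peaks$class]), c2$peaks$class)
  expect_equal(c1$peaks$fold_change, 1 / c2$peaks$fold_change, tolerance = 1e-12)
})

test_that("tightening thresholds never increases the differential count", {
  cfg <- small_config(seed = 13)
  cons <- build_consensus(simulate_peaks(cfg, simulate_genome(cfg))$peaks)
  n_diff <- function(fc, a) {
    sum(grepl("^differential", classify_peaks(cons, fc_threshold = fc,
                                              alpha = a)$peaks$class))
  }
  base <- n_diff(2, 0.05)
  expect_lte(n_diff(3, 0.05), base)
  expect_lte(n_diff(2, 0.01), base)
  expect_gte(n_diff(1.5, 0.05), base)
})

test_that("every consensus peak gets exactly one class", {
  cfg <- small_config(seed = 14, dropout_prob = 0.3)
  cls <- classify_peaks(build_consensus(simulate_peaks(cfg, simulate_genome(cfg))$peaks))
  expect_true(all(cls$peaks$class %in%
                    c("unique_A", "unique_B", "differential_up_A",
                      "differential_up_B", "shared", "unresolved")))
  expect_false(any(is.na(cls$peaks$class)))
})

test_that("peak annotation uses the midpoint", {
  g <- tiny_genome()
  # gA promoter ends at 1200 downstream boundary... peak straddling the
  # gA promoter/exon boundary with its midpoint inside the first exon
  pk <- data.frame(peak_id = "p1", chrom = "chrT", start = 1100L, end = 1500L,
                   stringsAsFactors = FALSE)
  ann <- annotate_peaks(pk, g)
  mid <- (1100 + 1500) %/% 2
  expect_equal(ann$feature, oracle_classify(mid, g)$category)
  # 200 random peaks agree with the per-base oracle at their midpoints
  set.seed(1)
  s <- sample.int(9500, 200)
  pks <- data.frame(peak_id = sprintf("r%d", 1:200), chrom = "chrT",
                    start = s, end = s + sample(100:400, 200, TRUE),
                    stringsAsFactors = FALSE)
  pks$end <- pmin(pks$end, 10000L)
  ann2 <- annotate_peaks(pks, g)
  mids <- (pks$start + pks$end) %/% 2
  oracle <- vapply(mids, function(m) oracle_classify(m, g)$category, "")
  expect_identical(ann2$feature, oracle)
})
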