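# The synthetic-data generator: determinism, planted structure, and the
# statistical properties downstream stages rely on.

test_that("genome simulation is byte-deterministic and places disjoint genes", {
  cfg <- simulation_config(seed = 1)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(simulation_config(seed = 1))
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g1, p1)
  write_gff3(g2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # brute-force O(n^2) pairwise overlap scan at the default size
  s <- g1$genes$start
  e <- g1$genes$end
  n <- length(s)
  for (i in seq_len(n - 1)) {
    expect_true(all(s[(i + 1):n] >= e[i] | e[(i + 1):n] <= s[i]))
  }
  expect_true(all(s >= 0 & e <= cfg$chrom_length))
  expect_true(all(e - s >= 2000 & e - s <= 10000))
})

test_that("gene models have 2-6 ordered exons spanning the gene", {
  g <- simulate_genome(small_config(seed = 3))
  for (id in g$genes$gene_id[1:20]) {
    ex <- g$exons[g$exons$gene_id == id, ]
    gene <- g$genes[g$genes$gene_id == id, ]
    expect_gte(nrow(ex), 2)
    expect_lte(nrow(ex), 6)
    expect_equal(min(ex$start), gene$start)
    expect_equal(max(ex$end), gene$end)
    expect_true(all(diff(ex$start) > 0))
  }
})

test_that("over-dense genomes fail with an explicit error", {
  expect_error(simulation_config(n_genes = 2000, chrom_length = 2e6),
               "genome too dense")
  # passes the coarse config check but cannot fit the drawn gene lengths
  expect_error(simulate_genome(simulation_config(n_genes = 900,
                                                 chrom_length = 2e6)),
               "genome too dense")
})

test_that("planted unique peaks obey the all-replicates membership rule", {
  cfg <- small_config(seed = 7)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  truth_B <- sim$truth$peaks[sim$truth$peaks$class == "unique_B", ]
  expect_equal(nrow(truth_B), cfg$n_unique_peaks_per_caste)
  # brute-force presence scan: >= 1 bp overlap with each replicate's set
  present_in <- function(peak, caste, rep) {
    d <- sim$peaks[sim$peaks$caste == caste & sim$peaks$replicate == rep, ]
    any(d$start < peak$end & peak$start < d$end)
  }
  for (i in seq_len(nrow(truth_B))) {
    pk <- truth_B[i, ]
    expect_true(all(vapply(1:3, function(r) present_in(pk, "W", r), TRUE)))
    expect_false(any(vapply(1:3, function(r) present_in(pk, "Q", r), TRUE)))
  }
})

test_that("forced promoter placement puts every caste-B unique midpoint in a promoter", {
  cfg <- small_config(seed = 2, frac_unique_in_promoter_casteB = 1.0)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  mids <- sim$truth$peaks$mid[sim$truth$peaks$class == "unique_B"]
  cl <- classify_position(mids, g, cfg$promoter_upstream, cfg$promoter_downstream)
  expect_true(all(cl$category == "promoter"))
})

test_that("dropout removes planted unique peaks from their own caste", {
  cfg <- small_config(seed = 4, dropout_prob = 1.0)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  uq <- sim$truth$peaks[sim$truth$peaks$class == "unique_A", ]
  called <- sim$peaks[sim$peaks$caste == "Q", ]
  for (i in seq_len(nrow(uq))) {
    expect_false(any(called$start < uq$end[i] & uq$start[i] < called$end))
  }
})

test_that("planted classes are exclusive and midpoints well separated", {
  cfg <- small_config(seed = 9)
  sim <- simulate_peaks(cfg, simulate_genome(cfg))
  tp <- sim$truth$peaks
  expect_equal(anyDuplicated(tp$peak_id), 0)
  expect_true(all(diff(sort(tp$mid)) >= 1100))
  expect_true(all(tp$start >= 0 & tp$end <= cfg$chrom_length))
  counts <- table(tp$class)
  expect_equal(unname(counts["background"]), cfg$n_background_peaks,
               ignore_attr = TRUE)
  expect_equal(sum(grepl("^differential", tp$class)), cfg$n_differential_peaks)
})

test_that("NB count noise matches the mean-dispersion relation", {
  set.seed(42)
  mu <- 100; alpha <- 0.05; n <- 5000
  x <- casteChIP:::rnbinom_mu(n, mu, alpha)
  expect_lt(abs(var(x) - (mu + alpha * mu^2)) / (mu + alpha * mu^2), 0.15)
  y <- casteChIP:::rnbinom_mu(n, mu, 0)
  expect_lt(abs(var(y) - mu) / mu, 0.15)
})

test_that("null fold-change planting yields near-zero differential recovery", {
  cfg <- small_config(seed = 6, planted_log2fc = 0)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  cls <- classify_peaks(build_consensus(sim$peaks))
  tp <- sim$truth$peaks
  diff_mids <- tp$mid[grepl("^differential", tp$class)]
  idx <- vapply(diff_mids, function(m) which.min(abs(cls$peaks$midpoint - m)), 1L)
  rec <- mean(grepl("^differential", cls$peaks$class[idx]))
  expect_lt(rec, 0.15)
})

test_that("expression simulation is deterministic and respects gene limits", {
  cfg <- small_config(seed = 8)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  e1 <- simulate_expression(cfg, g, sim$truth)
  e2 <- simulate_expression(cfg, g, sim$truth)
  expect_identical(e1$counts, e2$counts)
  expect_equal(sum(e1$truth$genes$de), cfg$n_de_genes)
  cfg_bad <- small_config(seed = 8, n_de_genes = 1000)
  expect_error(simulate_expression(cfg_bad, g, sim$truth), "exceeds")
})

test_that("zero de_log2fc makes planted-DE gene fold changes null-like", {
  ps <- replicate(3, NA_real_)
  for (s in 1:3) {
    cfg <- small_config(seed = 20 + s, de_log2fc = 0,
                        n_differential_peaks = 0)
    g <- simulate_genome(cfg)
    sim <- simulate_peaks(cfg, g)
    ex <- simulate_expression(cfg, g, sim$truth)
    de <- nb_diffexpr(ex$counts, ex$groups)
    lfc <- abs(de$log2_fold_change)
    ps[s] <- suppressWarnings(
      stats::ks.test(lfc[ex$truth$genes$de], lfc[!ex$truth$genes$de])$p.value)
  }
  expect_true(all(ps > 0.01))
})

test_that("planted signal-expression correlation tracks the target", {
  rhos <- vapply(1:3, function(s) {
    cfg <- simulation_config(seed = 30 + s, chrom_length = 4e6, n_genes = 300,
                             n_background_peaks = 0,
                             n_unique_peaks_per_caste = 0,
                             n_differential_peaks = 200,
                             frac_differential_in_promoter = 1,
                             n_de_genes = 0, signal_expression_rho = 0)
    g <- simulate_genome(cfg)
    sim <- simulate_peaks(cfg, g)
    ex <- simulate_expression(cfg, g, sim$truth)
    tr <- ex$truth
    linked <- !is.na(tr$genes$linked_peak)
    p_lfc <- tr$peaks$log2_fold_change[match(tr$genes$linked_peak[linked],
                                             tr$peaks$peak_id)]
    cor(p_lfc, tr$genes$log2_fold_change[linked], method = "spearman")
  }, 0)
  expect_lt(abs(mean(rhos)), 0.1)
})
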