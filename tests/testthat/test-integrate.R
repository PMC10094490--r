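# Peak-gene linking, overlaps, correlation, enrichment, metaprofile.

test_that("peaks link to at most one gene by midpoint containment", {
  g <- tiny_genome()
  pk <- data.frame(peak_id = c("prom", "body", "nowhere"),
                   chrom = "chrT",
                   start = c(400L, 2300L, 9600L),
                   end = c(600L, 2500L, 9900L),
                   stringsAsFactors = FALSE)
  links <- link_peaks_to_genes(pk, g)
  expect_equal(nrow(links), 2)
  expect_equal(links$gene_id[links$peak_id == "prom"], "gA")
  expect_equal(links$link_type[links$peak_id == "prom"], "promoter")
  expect_equal(links$link_type[links$peak_id == "body"], "gene_body")
  expect_false("nowhere" %in% links$peak_id)
})

test_that("random peak links agree with the per-base oracle", {
  g <- tiny_genome()
  set.seed(3)
  s <- sample.int(9400, 300)
  pk <- data.frame(peak_id = sprintf("p%d", 1:300), chrom = "chrT",
                   start = s, end = s + 200L, stringsAsFactors = FALSE)
  links <- link_peaks_to_genes(pk, g)
  for (i in seq_len(nrow(pk))) {
    o <- oracle_classify((pk$start[i] + pk$end[i]) %/% 2, g)
    if (o$category == "intergenic") {
      expect_false(pk$peak_id[i] %in% links$peak_id)
    } else {
      row <- links[links$peak_id == pk$peak_id[i], ]
      expect_equal(row$gene_id, o$gene_id)
      expect_equal(row$link_type,
                   if (o$category == "promoter") "promoter" else "gene_body")
    }
  }
})

test_that("overlap summaries are exact, commutative and idempotent", {
  expect_equal(overlap_sets(c("a", "b"), c("c", "d"))$intersection, 0)
  expect_equal(overlap_sets(c("a", "b"), c("a", "b"))$intersection, 2)
  o1 <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  o2 <- overlap_sets(c("b", "c", "d"), c("a", "b", "c"))
  expect_equal(o1$intersection, o2$intersection)
  expect_equal(o1$jaccard, 0.5)
  expect_equal(overlap_sets(c("a", "a", "b"), c("b", "b"))$n1, 2)
})

test_that("Spearman correlation matches the rank-difference formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- spearman_cor(x, y)
  d2 <- sum((rank(x) - rank(y))^2)
  rho_hand <- 1 - 6 * d2 / (5 * (25 - 1))
  expect_equal(r$rho, rho_hand, tolerance = 1e-12)
  expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  t_hand <- rho_hand * sqrt(3 / (1 - rho_hand^2))
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)

  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$rho, -1)
  expect_equal(spearman_cor(1:10, rev(1:10))$p_value, 0)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("signal-expression correlation errors without linked pairs", {
  g <- tiny_genome()
  pk <- data.frame(peak_id = "p1", chrom = "chrT", start = 9600L, end = 9900L,
                   class = "differential_up_A", log2_fold_change = 2,
                   stringsAsFactors = FALSE)
  links <- link_peaks_to_genes(pk, g)
  de <- data.frame(gene_id = c("gA", "gB"), log2_fold_change = c(1, -1),
                   deg = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_error(signal_expression_correlation(pk, links, de), "no linked pairs")
})

test_that("hypergeometric enrichment matches direct combinatorial summation", {
  r <- hypergeometric_enrichment(paste0("g", 1:5),
                                 list(hit = paste0("g", 1:5)),
                                 paste0("g", 1:20))
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # cross-check by summing the PMF over the tail
  direct <- sum(vapply(5:5, function(k) {
    choose(5, k) * choose(15, 5 - k) / choose(20, 5)
  }, 0))
  expect_equal(r$p_value, direct, tolerance = 1e-12)

  # disjoint query: P(X >= 0) = 1
  r0 <- hypergeometric_enrichment(paste0("g", 6:10),
                                  list(miss = paste0("g", 1:5)),
                                  paste0("g", 1:20))
  expect_equal(r0$p_value, 1)

  # tail identity p = 1 - CDF(k - 1) against PMF summation, random cases
  set.seed(11)
  for (i in 1:20) {
    N <- sample(20:60, 1); K <- sample(3:15, 1); n <- sample(3:15, 1)
    universe <- paste0("u", seq_len(N))
    set_genes <- sample(universe, K)
    query <- sample(universe, n)
    k <- length(intersect(query, set_genes))
    r <- hypergeometric_enrichment(query, list(s = set_genes), universe)
    direct <- sum(vapply(k:min(K, n), function(kk) {
      choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
    }, 0))
    expect_equal(r$p_value, direct, tolerance = 1e-10)
  }
})

test_that("TSS metaprofile is flat under uniform coverage and strand-aware", {
  g <- tiny_genome()
  uniform <- data.frame(chrom = "chrT", start = 0L, end = 10000L, value = 3,
                        stringsAsFactors = FALSE)
  prof <- tss_metaprofile(uniform, g, flank = 500, bin_size = 50)
  expect_true(all(abs(prof$mean_signal - 3) < 1e-12))

  # signal only upstream of the minus-strand gene gB (coordinates above
  # its TSS at 5999) must appear at negative offsets
  up <- data.frame(chrom = "chrT", start = 6100L, end = 6400L, value = 5,
                   stringsAsFactors = FALSE)
  g_minus <- genome_annotation(g$chromosomes,
                               g$genes[g$genes$gene_id == "gB", ],
                               g$exons[g$exons$gene_id == "gB", ])
  prof2 <- tss_metaprofile(up, g_minus, flank = 500, bin_size = 50)
  expect_true(all(prof2$mean_signal[prof2$offset >= 0] == 0))
  expect_gt(sum(prof2$mean_signal[prof2$offset < 0]), 0)

  empty <- genome_annotation(g$chromosomes,
                             g$genes[0, ], g$exons[0, ])
  expect_error(tss_metaprofile(uniform, empty, 500, 50), "no genes")
})
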