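# Peak-gene-expression integration: peak-to-gene assignment, set overlap,
# Spearman correlation, hypergeometric over-representation, and TSS
# metaprofiles.

#' Assign peaks to genes by midpoint containment
#'
#' A peak links to at most one gene: to the gene whose promoter window
#' contains the peak midpoint (link type `"promoter"`), else to the gene
#' whose span contains it (`"gene_body"`); intergenic midpoints yield no
#' link. Ties are broken by nearest TSS, then lexicographic gene id (via
#' [classify_position()]).
#'
#' @param peaks data.frame with `peak_id`, `chrom`, `start`, `end`, or a
#'   `consensus_peaks` object.
#' @param genome a [genome_annotation()].
#' @param upstream,downstream promoter window extent.
#' @return data.frame with columns `peak_id`, `gene_id`, `link_type`,
#'   `dist_tss` (signed bases; negative = upstream of the TSS).
#' @export
link_peaks_to_genes <- function(peaks, genome, upstream = 2000, downstream = 200) {
  df <- if (inherits(peaks, "consensus_peaks")) peaks$peaks else peaks
  mid <- (df$start + df$end) %/% 2L
  cl <- classify_position(data.frame(chrom = df$chrom, pos = mid,
                                     stringsAsFactors = FALSE),
                          genome, upstream, downstream)
  keep <- cl$category != "intergenic"
  data.frame(peak_id = df$peak_id[keep],
             gene_id = cl$gene_id[keep],
             link_type = ifelse(cl$category[keep] == "promoter",
                                "promoter", "gene_body"),
             dist_tss = cl$dist_tss[keep],
             stringsAsFactors = FALSE)
}

#' Overlap summary of two gene sets
#'
#' @param genes1,genes2 character vectors of gene ids (duplicates ignored).
#' @return list with `n1`, `n2`, `intersection` (count), `jaccard`, and
#'   the intersecting `genes`.
#' @export
overlap_sets <- function(genes1, genes2) {
  g1 <- unique(genes1)
  g2 <- unique(genes2)
  common <- intersect(g1, g2)
  un <- union(g1, g2)
  list(n1 = length(g1), n2 = length(g2),
       intersection = length(common),
       jaccard = if (length(un)) length(common) / length(un) else NA_real_,
       genes = sort(common))
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (ties allowed); the
#' p-value uses the large-sample approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return object of class `correlation_result`: list with `rho`, `n`,
#'   `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs, got %d", n)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, n = n, p_value = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.4g)\n", x$rho, x$n, x$p_value))
  invisible(x)
}

#' Correlation between differential peak signal and expression change
#'
#' Pairs each gene's ChIP fold change with its expression fold change,
#' both in the same caste-A-over-caste-B orientation, over genes linked to
#' differential-class peaks (mean peak log2FC when a gene owns several).
#' Two variants are reported: all linked genes, and the restriction to
#' DEGs.
#'
#' @param classified a [classify_peaks()] object (annotated or not).
#' @param links a [link_peaks_to_genes()] data.frame.
#' @param de_result a [nb_wald_test()] data.frame.
#' @return list with `all` and `deg_only` [spearman_cor()] results
#'   (`deg_only` is `NULL` when fewer than 3 DEG pairs exist) and the
#'   underlying `pairs` data.frame.
#' @export
signal_expression_correlation <- function(classified, links, de_result) {
  pk <- if (inherits(classified, "consensus_peaks")) classified$peaks else classified
  diff_pk <- pk[grepl("^differential", pk$class), , drop = FALSE]
  lk <- links[links$peak_id %in% diff_pk$peak_id, , drop = FALSE]
  if (!nrow(lk)) stopf("no linked pairs: no differential peak links to a gene")
  lfc <- diff_pk$log2_fold_change[match(lk$peak_id, diff_pk$peak_id)]
  peak_lfc <- tapply(lfc, lk$gene_id, mean)
  genes <- names(peak_lfc)
  m <- match(genes, de_result$gene_id)
  ok <- !is.na(m)
  pairs <- data.frame(gene_id = genes[ok],
                      peak_log2_fold_change = as.numeric(peak_lfc[ok]),
                      expr_log2_fold_change = de_result$log2_fold_change[m[ok]],
                      deg = de_result$deg[m[ok]],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3L) stopf("no linked pairs: fewer than 3 genes with both measures")
  res_all <- spearman_cor(pairs$peak_log2_fold_change, pairs$expr_log2_fold_change)
  res_deg <- NULL
  if (sum(pairs$deg) >= 3L) {
    res_deg <- spearman_cor(pairs$peak_log2_fold_change[pairs$deg],
                            pairs$expr_log2_fold_change[pairs$deg])
  }
  list(all = res_all, deg_only = res_deg, pairs = pairs)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test `P(X >= k)` of a query gene list against
#' each user-supplied gene set, within a stated universe, with BH
#' adjustment across sets. Genes outside the universe are dropped from
#' both query and sets before testing.
#'
#' @param query character vector of query gene ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all eligible gene ids.
#' @return data.frame with columns `set`, `overlap` (k), `set_size` (K),
#'   `query_size` (n), `universe_size` (N), `p_value`, `p_adj`.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  q <- intersect(unique(query), universe)
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(q, s))
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = length(q), universe_size = length(universe),
               p_value = stats::phyper(k - 1, length(s),
                                       length(universe) - length(s),
                                       length(q), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Average signal metaprofile around gene TSSs
#'
#' Bins the +/- `flank` region around every gene's TSS into `bin_size`-bp
#' bins, strand-flipped so that negative offsets are always upstream, and
#' averages per-base coverage per bin across genes. Bins extending past a
#' chromosome edge are dropped for that gene only.
#'
#' @param signal bedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `value`), e.g. from [read_bedgraph()] or [peak_coverage()].
#' @param genome a [genome_annotation()] with at least one gene.
#' @param flank half-width of the window in bases (default 2000).
#' @param bin_size bin width in bases (default 50).
#' @return data.frame with columns `offset` (bin start relative to the
#'   TSS), `mean_signal`, `n_genes` (genes contributing to the bin).
#' @export
tss_metaprofile <- function(signal, genome, flank = 2000, bin_size = 50) {
  if (!nrow(genome$genes)) stopf("annotation has no genes")
  nbin <- 2L * as.integer(flank %/% bin_size)
  offsets <- (seq_len(nbin) - 1L - nbin %/% 2L) * bin_size
  sums <- numeric(nbin)
  counts <- integer(nbin)
  for (ch in unique(genome$genes$chrom)) {
    sg <- signal[signal$chrom == ch, , drop = FALSE]
    len <- genome$chromosomes$length[match(ch, genome$chromosomes$name)]
    gch <- genome$genes[genome$genes$chrom == ch, , drop = FALSE]
    max_end <- max(c(sg$end, gch$end + flank + bin_size))
    if (is.na(len)) len <- max_end
    cov <- numeric(0)
    if (nrow(sg)) {
      cov_rle <- IRanges::coverage(IRanges::IRanges(sg$start + 1L, sg$end),
                                   weight = sg$value, width = max(len, max_end))
    } else {
      cov_rle <- S4Vectors::Rle(0, max(len, max_end))
    }
    for (i in seq_len(nrow(gch))) {
      plus <- gch$strand[i] == "+"
      tss <- if (plus) gch$start[i] else gch$end[i] - 1L
      # canonical [s, e) covered by each bin, after strand flip
      if (plus) {
        s <- tss + offsets
        e <- s + bin_size
      } else {
        e <- tss - offsets + 1L
        s <- e - bin_size
      }
      ok <- s >= 0 & e <= len
      if (!any(ok)) next
      v <- IRanges::viewMeans(IRanges::Views(cov_rle, start = s[ok] + 1L,
                                             end = e[ok]))
      sums[ok] <- sums[ok] + as.numeric(v)
      counts[ok] <- counts[ok] + 1L
    }
  }
  data.frame(offset = offsets,
             mean_signal = ifelse(counts > 0, sums / counts, NA_real_),
             n_genes = counts)
}
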