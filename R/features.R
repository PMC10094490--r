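# Promoter geometry and point-in-feature classification. Everything here
# works in the canonical 0-based half-open convention.

#' Strand-aware promoter windows around gene TSSs
#'
#' For a `+` gene the window is `[TSS - upstream, TSS + downstream)` with
#' the TSS at the gene start; for a `-` gene the TSS is the gene's last
#' base and the window is `[end - downstream, end + upstream)`. Windows are
#' clipped to chromosome bounds. A degenerate zero-width request
#' (`upstream = downstream = 0`) returns a minimal 1-base window at the
#' TSS, keeping sweeps over window sizes total.
#'
#' @param genome a [genome_annotation()].
#' @param upstream bases upstream of the TSS (default 2000).
#' @param downstream bases downstream of the TSS (default 200).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (0-based position of the TSS base).
#' @export
promoter_windows <- function(genome, upstream = 2000, downstream = 200) {
  check_number(upstream, "upstream", min = 0)
  check_number(downstream, "downstream", min = 0)
  g <- genome$genes
  plus <- g$strand == "+"
  tss <- ifelse(plus, g$start, g$end - 1L)
  start <- ifelse(plus, g$start - upstream, g$end - downstream)
  end <- ifelse(plus, g$start + downstream, g$end + upstream)
  degenerate <- start >= end
  start[degenerate] <- tss[degenerate]
  end[degenerate] <- tss[degenerate] + 1L
  len <- genome$chromosomes$length[match(g$chrom, genome$chromosomes$name)]
  start <- pmax(start, 0L)
  end <- ifelse(is.na(len), end, pmin(end, len))
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = g$strand, tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

#' Classify genomic positions into promoter/exon/intron/intergenic
#'
#' Categories follow the fixed precedence promoter > exon > intron >
#' intergenic, so the three gene-linked categories are mutually exclusive.
#' When a position falls in features of the same precedence belonging to
#' several genes, the gene with the nearest TSS wins, with lexicographic
#' gene id as the final tie-break, making the assignment deterministic.
#'
#' @param positions data.frame with columns `chrom` and `pos` (0-based
#'   base positions), or a numeric vector of positions when the annotation
#'   has a single chromosome.
#' @param genome a [genome_annotation()].
#' @param upstream,downstream promoter window extent, see
#'   [promoter_windows()].
#' @return data.frame with columns `chrom`, `pos`, `category` (one of
#'   `"promoter"`, `"exon"`, `"intron"`, `"intergenic"`), `gene_id`
#'   (`NA` for intergenic) and `dist_tss` (signed bases to the assigned
#'   gene's TSS; negative = upstream).
#' @export
classify_position <- function(positions, genome, upstream = 2000, downstream = 200) {
  if (is.numeric(positions)) {
    if (nrow(genome$chromosomes) != 1L) {
      stopf("bare positions need a single-chromosome annotation; pass a data.frame")
    }
    positions <- data.frame(chrom = genome$chromosomes$name[1], pos = positions,
                            stringsAsFactors = FALSE)
  }
  n <- nrow(positions)
  out <- data.frame(chrom = positions$chrom, pos = positions$pos,
                    category = rep("intergenic", n),
                    gene_id = rep(NA_character_, n),
                    dist_tss = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n || !nrow(genome$genes)) return(out)

  prom <- promoter_windows(genome, upstream, downstream)
  introns <- intron_intervals(genome)
  g <- genome$genes
  tss_of <- stats::setNames(prom$tss, prom$gene_id)
  strand_of <- stats::setNames(g$strand, g$gene_id)

  assign_layer <- function(feat, unassigned) {
    # feat: data.frame(gene_id, chrom, start, end); returns indices assigned
    if (!nrow(feat) || !any(unassigned)) return(logical(n))
    hit <- logical(n)
    for (ch in unique(positions$chrom[unassigned])) {
      pi <- which(unassigned & positions$chrom == ch)
      fi <- which(feat$chrom == ch)
      if (!length(pi) || !length(fi)) next
      q <- IRanges::IRanges(positions$pos[pi] + 1L, width = 1L)
      s <- IRanges::IRanges(feat$start[fi] + 1L, feat$end[fi])
      ov <- IRanges::findOverlaps(q, s)
      if (!length(ov)) next
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      gene <- feat$gene_id[fi[sh]]
      pos <- positions$pos[pi[qh]]
      dist <- abs(pos - tss_of[gene])
      ord <- order(qh, dist, gene)
      keep <- ord[!duplicated(qh[ord])]
      idx <- pi[qh[keep]]
      out$gene_id[idx] <<- gene[keep]
      hit[idx] <- TRUE
    }
    hit
  }

  is_prom <- assign_layer(prom[, c("gene_id", "chrom", "start", "end")], rep(TRUE, n))
  out$category[is_prom] <- "promoter"
  un <- !is_prom
  is_exon <- assign_layer(genome$exons[, c("gene_id", "chrom", "start", "end")], un)
  out$category[is_exon] <- "exon"
  un <- un & !is_exon
  is_intron <- assign_layer(introns[, c("gene_id", "chrom", "start", "end")], un)
  out$category[is_intron] <- "intron"

  has_gene <- !is.na(out$gene_id)
  if (any(has_gene)) {
    tss <- tss_of[out$gene_id[has_gene]]
    sgn <- ifelse(strand_of[out$gene_id[has_gene]] == "+", 1, -1)
    out$dist_tss[has_gene] <- sgn * (out$pos[has_gene] - tss)
  }
  out
}
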