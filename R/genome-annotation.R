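#' Genome annotation container
#'
#' Holds gene models on one or more chromosomes. All coordinates are stored
#' in the package's canonical convention, 0-based half-open (BED-like);
#' conversion from/to the 1-based closed GFF3 convention happens only in
#' [read_gff3()] and [write_gff3()].
#'
#' @param chromosomes data.frame with columns `name` and `length` (bases;
#'   may be `NA` when unknown).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes, exons) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) {
      stopf("duplicate gene ids: %s",
            paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stopf("gene strand must be '+' or '-'")
    }
    if (any(genes$start < 0) || any(genes$start >= genes$end)) {
      stopf("gene intervals must satisfy 0 <= start < end")
    }
    len <- chromosomes$length[match(genes$chrom, chromosomes$name)]
    bad <- !is.na(len) & genes$end > len
    if (any(bad)) stopf("gene '%s' extends beyond its chromosome", genes$gene_id[bad][1])
    genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL
  }
  if (nrow(exons)) {
    g <- match(exons$gene_id, genes$gene_id)
    if (anyNA(g)) stopf("exon refers to unknown gene '%s'", exons$gene_id[which(is.na(g))[1]])
    within <- exons$start >= genes$start[g] & exons$end <= genes$end[g]
    if (!all(within)) {
      stopf("exon outside gene bounds for gene '%s'", exons$gene_id[!within][1])
    }
    exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # exons must not overlap within a gene
    by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
    for (idx in by_gene) {
      if (length(idx) > 1L) {
        s <- exons$start[idx]; e <- exons$end[idx]
        if (any(s[-1] < e[-length(e)])) {
          stopf("overlapping exons within gene '%s'", exons$gene_id[idx[1]])
        }
      }
    }
  }
  structure(list(chromosomes = chromosomes, genes = genes, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %d gene(s), %d exon(s)\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Intron intervals implied by a gene's exon structure
#'
#' @param genome a [genome_annotation()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (canonical 0-based half-open), one row per intron.
#' @export
intron_intervals <- function(genome) {
  ex <- genome$exons
  if (!nrow(ex)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  }
  out <- lapply(split(ex, ex$gene_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = d$end[-nrow(d)], end = d$start[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  }
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}
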