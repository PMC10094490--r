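#' Simulate a single-chromosome gene annotation
#'
#' Places `n_genes` non-overlapping genes on one chromosome, each with
#' 2-6 exons and a length uniform in [2000, 10000] bases, strand chosen at
#' random. Placement allocates the free (intergenic) space among the gaps
#' by a stick-breaking draw, which guarantees disjoint genes in one pass;
#' when the genes cannot fit, an explicit "genome too dense" error is
#' raised. Byte-identical output for identical configurations.
#'
#' @param config a [simulation_config()].
#' @return a [genome_annotation()] with chromosome `"chrS"`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  L <- config$chrom_length
  chroms <- data.frame(name = "chrS", length = L, stringsAsFactors = FALSE)
  if (n == 0) {
    return(genome_annotation(chroms,
                             data.frame(gene_id = character(), chrom = character(),
                                        start = integer(), end = integer(),
                                        strand = character()),
                             data.frame(gene_id = character(), chrom = character(),
                                        start = integer(), end = integer())))
  }
  lens <- sample(2000:10000, n, replace = TRUE)
  min_gap <- 1L
  slack <- L - sum(lens) - n * min_gap
  if (slack < 0) {
    stopf("genome too dense: %d genes totalling %d bases exceed chromosome length %g",
          n, sum(lens), L)
  }
  cuts <- sort(stats::runif(n, 0, slack))
  extra <- floor(diff(c(0, cuts)))
  gaps <- min_gap + extra
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene_%04d", seq_len(n))
  genes <- data.frame(gene_id = gene_id, chrom = "chrS",
                      start = starts, end = starts + lens, strand = strand,
                      stringsAsFactors = FALSE)
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(2:6, 1)
    n_seg <- 2L * n_ex - 1L
    min_seg <- 50L
    w <- stats::runif(n_seg)
    seg <- floor(w / sum(w) * (lens[i] - min_seg * n_seg)) + min_seg
    seg[n_seg] <- seg[n_seg] + (lens[i] - sum(seg))
    ends <- cumsum(seg)
    seg_start <- c(0L, ends[-n_seg])
    is_exon <- seq_len(n_seg) %% 2L == 1L
    exon_list[[i]] <- data.frame(gene_id = gene_id[i], chrom = "chrS",
                                 start = starts[i] + seg_start[is_exon],
                                 end = starts[i] + ends[is_exon],
                                 stringsAsFactors = FALSE)
  }
  genome_annotation(chroms, genes, do.call(rbind, exon_list))
}
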