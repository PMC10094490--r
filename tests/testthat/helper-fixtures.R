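# Shared fixtures: all synthetic, built in code at test time.

# A small but complete simulation: quick enough to run many times.
small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, chrom_length = 1.2e6, n_genes = 120,
                   n_background_peaks = 80, n_unique_peaks_per_caste = 15,
                   n_differential_peaks = 20, n_de_genes = 25)
  simulation_config_from(utils::modifyList(defaults, list(...)))
}

simulation_config_from <- function(args) do.call(simulation_config, args)

# A tiny hand-built annotation on an 10 kb chromosome, with a + gene, a -
# gene, and a pair close enough that one gene's promoter window reaches
# into its neighbour's body (exercises precedence and tie-breaks).
tiny_genome <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chrT",
    start = c(1000L, 4000L, 7000L),
    end = c(3000L, 6000L, 9500L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gC", "gC"),
    chrom = "chrT",
    start = c(1000L, 2200L, 4000L, 5300L, 7000L, 7900L, 9000L),
    end = c(1800L, 3000L, 5000L, 6000L, 7600L, 8500L, 9500L),
    stringsAsFactors = FALSE)
  genome_annotation(data.frame(name = "chrT", length = 10000), genes, exons)
}

# Independent per-base category oracle: exhaustive scan over all features
# with the promoter > exon > intron precedence and nearest-TSS /
# lexicographic tie-breaks, written from the rule, not the implementation.
oracle_classify <- function(pos, genome, upstream = 2000, downstream = 200) {
  g <- genome$genes
  chrom_len <- genome$chromosomes$length[1]
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  candidates <- function(layer_test) {
    hits <- which(vapply(seq_len(nrow(g)), layer_test, TRUE))
    if (!length(hits)) return(NA_character_)
    d <- abs(pos - tss[hits])
    hits <- hits[order(d, g$gene_id[hits])]
    g$gene_id[hits[1]]
  }
  in_promoter <- function(i) {
    if (g$strand[i] == "+") {
      lo <- max(0, g$start[i] - upstream); hi <- min(chrom_len, g$start[i] + downstream)
    } else {
      lo <- max(0, g$end[i] - downstream); hi <- min(chrom_len, g$end[i] + upstream)
    }
    pos >= lo && pos < hi
  }
  in_exon <- function(i) {
    e <- genome$exons[genome$exons$gene_id == g$gene_id[i], ]
    any(pos >= e$start & pos < e$end)
  }
  in_gene <- function(i) pos >= g$start[i] && pos < g$end[i]
  gp <- candidates(in_promoter)
  if (!is.na(gp)) return(list(category = "promoter", gene_id = gp))
  ge <- candidates(function(i) in_exon(i))
  if (!is.na(ge)) return(list(category = "exon", gene_id = ge))
  gi <- candidates(function(i) in_gene(i) && !in_exon(i))
  if (!is.na(gi)) return(list(category = "intron", gene_id = gi))
  list(category = "intergenic", gene_id = NA_character_)
}
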