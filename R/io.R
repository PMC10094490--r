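# Readers and writers for the plain-text genomics formats used throughout:
# GFF3 (1-based closed), BED6 and bedGraph (0-based half-open), counts and
# Ct TSVs, and GMT gene-set files. Parsing of the standard formats is
# delegated to rtracklayer after a light line-level validation pass that
# supplies line-numbered error messages. Coordinate conventions are
# converted here, at the boundary, and nowhere else.

validate_tabular_lines <- function(path, min_fields, what) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf < min_fields) {
      stopf("malformed %s line %d in '%s': %d field(s), expected >= %d",
            what, i, path, nf, min_fields)
    }
  }
  lines
}

#' Read a GFF3 gene annotation
#'
#' Expects `gene` and `exon` features with `ID`/`Parent` attributes, as
#' written by [write_gff3()] or any standards-compliant tool. Chromosome
#' lengths are taken from `##sequence-region` directives when present.
#' GFF3's 1-based closed coordinates are converted to the canonical 0-based
#' half-open convention on read.
#'
#' @param path path to a GFF3 file (gzip accepted).
#' @return a [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  lines <- validate_tabular_lines(path, 9L, "GFF3")
  sr <- grep("^##sequence-region", lines, value = TRUE)
  chroms <- data.frame(name = character(), length = numeric())
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    chroms <- data.frame(
      name = vapply(parts, `[`, "", 2L),
      length = as.numeric(vapply(parts, `[`, "", 4L)),
      stringsAsFactors = FALSE
    )
  }
  has_features <- any(!grepl("^(#|\\s*$)", lines))
  if (!has_features) {
    return(genome_annotation(chroms,
                             data.frame(gene_id = character(), chrom = character(),
                                        start = integer(), end = integer(),
                                        strand = character()),
                             data.frame(gene_id = character(), chrom = character(),
                                        start = integer(), end = integer())))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- as.character(gr$type) == "gene"
  is_exon <- as.character(gr$type) == "exon"
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    stringsAsFactors = FALSE
  )
  parent <- vapply(gr$Parent[is_exon], function(p) {
    if (!length(p)) NA_character_ else as.character(p[[1]])
  }, "")
  exons <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)[is_exon]),
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE
  )
  if (anyNA(exons$gene_id)) stopf("exon without Parent attribute in '%s'", path)
  if (!nrow(chroms)) {
    chroms <- data.frame(name = unique(genes$chrom), length = NA_real_,
                         stringsAsFactors = FALSE)
  }
  genome_annotation(chroms, genes, exons)
}

#' Write a GFF3 gene annotation
#'
#' Deterministic, byte-stable output: fixed header, genes in coordinate
#' order, each followed by its exons. Canonical half-open coordinates are
#' converted to GFF3's 1-based closed convention on write.
#'
#' @param genome a [genome_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ch <- genome$chromosomes
  for (i in seq_len(nrow(ch))) {
    if (!is.na(ch$length[i])) {
      writeLines(sprintf("##sequence-region %s 1 %d", ch$name[i],
                         as.integer(ch$length[i])), con)
    }
  }
  g <- genome$genes
  ex <- genome$exons
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tcasteChIP\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    e <- ex[ex$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(e)) {
      writeLines(sprintf("%s\tcasteChIP\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         e$chrom, e$start + 1L, e$end, g$strand[i],
                         g$gene_id[i], seq_len(nrow(e)), g$gene_id[i]), con)
    }
  }
  invisible(path)
}

#' Read a BED file of peak intervals
#'
#' BED is already 0-based half-open, the canonical convention, so
#' coordinates pass through unchanged. The score column, when present,
#' carries the mean signal (read count) in the interval and is not clamped
#' to the UCSC 0-1000 range.
#'
#' @param path path to a BED file (gzip accepted).
#' @param genome optional [genome_annotation()]; intervals on chromosomes
#'   absent from it trigger a warning only (peak files may legitimately
#'   precede an annotation).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- validate_tabular_lines(path, 3L, "BED")
  data_lines <- lines[!grepl("^(#|track|browser|\\s*$)", lines)]
  if (!length(data_lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  out$strand[out$strand == "*"] <- "."
  if (any(out$start >= out$end)) {
    stopf("invalid BED interval with start >= end in '%s'", path)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(out$chrom), genome$chromosomes$name)
    if (length(unknown)) {
      warning(sprintf("BED chromosomes not in annotation: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  out
}

#' Write peak intervals as BED6
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  if (any(peaks$start >= peaks$end)) stopf("invalid interval with start >= end")
  n <- nrow(peaks)
  name <- peaks$name %||% rep(".", n)
  score <- peaks$score %||% rep(0, n)
  strand <- peaks$strand %||% rep(".", n)
  name[is.na(name)] <- "."
  score[is.na(score)] <- 0
  strand[is.na(strand) | strand == "*"] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  if (n) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom,
                       as.integer(peaks$start), as.integer(peaks$end),
                       name, fmt_num(score, 10), strand), con)
  }
  invisible(path)
}

#' Read a 4-column bedGraph signal track
#'
#' @param path path to a bedGraph file (gzip accepted).
#' @return data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  validate_tabular_lines(path, 4L, "bedGraph")
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
}

#' Write a 4-column bedGraph signal track
#'
#' @param signal data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(signal)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", signal$chrom,
                       as.integer(signal$start), as.integer(signal$end),
                       fmt_num(signal$value, 10)), con)
  }
  invisible(path)
}

#' Read a gene-by-sample count table
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @return integer matrix with gene ids as rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stopf("counts table must have a 'gene_id' column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stopf("negative entries in count table '%s'", path)
  m
}

#' Write a gene-by-sample count table
#'
#' @param counts numeric matrix with gene ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample`, `group`, `gene`, `ct`.
#' @return data.frame with those columns.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(df))) {
    stopf("Ct table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$ct <= 0)) stopf("Ct values must be positive")
  df[, need]
}

#' Write a qPCR Ct table
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("malformed GMT line: '%s'", substr(ln, 1, 50))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  sets
}
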