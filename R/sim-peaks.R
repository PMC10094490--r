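# Planted replicate peak sets. Castes are labelled "Q" (caste A) and "W"
# (caste B). Planted peaks are 1 kb wide with <= 50 bp per-replicate
# jitter, and midpoints are kept >= 1200 bp apart so that consensus
# merging can never fuse two planted peaks (1000 bp width + 2 x 50 bp
# jitter < 1200), keeping planted classes mutually exclusive.

PEAK_HALF_WIDTH <- 500L
PEAK_JITTER <- 50L
PEAK_MIN_SEP <- 1200L

# Per-base feature category codes for fast planting:
# 0 intergenic, 1 promoter, 2 exon, 3 intron (promoter > exon > intron).
feature_code_vector <- function(genome, upstream, downstream) {
  L <- as.integer(genome$chromosomes$length[1])
  code <- integer(L)
  paint <- function(df, value) {
    for (i in seq_len(nrow(df))) {
      s <- max(df$start[i], 0L) + 1L
      e <- min(df$end[i], L)
      if (s <= e) code[s:e] <<- value
    }
  }
  paint(intron_intervals(genome), 3L)
  paint(genome$exons, 2L)
  paint(promoter_windows(genome, upstream, downstream), 1L)
  code
}

#' Simulate replicate ChIP peak sets with planted ground truth
#'
#' Plants three peak populations on the simulated genome:
#' \itemize{
#'   \item background peaks, present in every replicate of both castes
#'     with equal NB means;
#'   \item caste-unique peaks, present in all replicates of their own
#'     caste and in none of the other (unless `dropout_prob` fires),
#'     with the configured fractions placed in promoter windows (caste B)
#'     or introns (caste A), the remainder at random positions;
#'   \item differential peaks, present in both castes with NB means
#'     differing by a planted log2 fold change (per-peak magnitude
#'     `planted_log2fc` +/- 20%, signs split evenly between castes), a
#'     configurable fraction centred on promoter TSSs.
#' }
#' Promoter-planted peaks are centred within 150 bp of the TSS, so
#' aggregate signal peaks at the TSS. Each replicate's intervals are the
#' planted 1 kb window shifted by an independent jitter of up to 50 bp;
#' the BED score column carries the replicate's NB read count.
#'
#' @param config a [simulation_config()].
#' @param genome the matching [simulate_genome()] annotation.
#' @return list with `peaks` (long data.frame: `caste`, `replicate`,
#'   `chrom`, `start`, `end`, `name`, `score`) and `truth` (a
#'   `truth_manifest`: planted peak table, per-class counts, parameters).
#' @export
simulate_peaks <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2L))
  L <- as.integer(config$chrom_length)
  hw <- PEAK_HALF_WIDTH
  margin <- hw + PEAK_JITTER
  code <- feature_code_vector(genome, config$promoter_upstream,
                              config$promoter_downstream)
  prom <- promoter_windows(genome, config$promoter_upstream,
                           config$promoter_downstream)
  introns <- intron_intervals(genome)
  accepted <- integer(0)

  propose <- function(target) {
    # returns c(pos, code) or NULL; gene id handled by caller for promoters
    if (target == "promoter") {
      if (!nrow(prom)) stopf("insufficient feature space: no promoters to plant in")
      gi <- sample.int(nrow(prom), 1)
      pos <- prom$tss[gi] + sample.int(301L, 1) - 151L
      list(pos = pos, gene = prom$gene_id[gi])
    } else if (target == "intron") {
      if (!nrow(introns)) stopf("insufficient feature space: no introns to plant in")
      gi <- sample.int(nrow(introns), 1)
      pos <- introns$start[gi] + sample.int(introns$end[gi] - introns$start[gi], 1) - 1L
      list(pos = pos, gene = introns$gene_id[gi])
    } else {
      list(pos = sample.int(L - 2L * margin, 1) + margin, gene = NA_character_)
    }
  }

  place <- function(n, target) {
    out_pos <- integer(n)
    out_gene <- character(n)
    out_cat <- character(n)
    cats <- c("intergenic", "promoter", "exon", "intron")
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        cand <- propose(target)
        pos <- cand$pos
        if (pos < margin || pos > L - margin) next
        if (length(accepted) && min(abs(accepted - pos)) < PEAK_MIN_SEP) next
        cat_i <- cats[code[pos + 1L] + 1L]
        if (target == "promoter" && cat_i != "promoter") next
        if (target == "intron" && cat_i != "intron") next
        accepted <<- c(accepted, pos)
        out_pos[i] <- pos
        out_gene[i] <- cand$gene
        out_cat[i] <- cat_i
        ok <- TRUE
        break
      }
      if (!ok) {
        stopf("insufficient space to plant %d '%s' peak(s); reduce peak numbers or enlarge the genome",
              n, target)
      }
    }
    data.frame(mid = out_pos, gene_id = out_gene, feature = out_cat,
               stringsAsFactors = FALSE)
  }

  plant_group <- function(n, frac, feat) {
    n_feat <- round(frac * n)
    rbind(if (n_feat > 0) place(n_feat, feat),
          if (n - n_feat > 0) place(n - n_feat, "any"))
  }

  n_uq <- config$n_unique_peaks_per_caste
  n_diff <- config$n_differential_peaks
  bg <- if (config$n_background_peaks > 0) place(config$n_background_peaks, "any")
  uqA <- if (n_uq > 0) plant_group(n_uq, config$frac_unique_in_intron_casteA, "intron")
  uqB <- if (n_uq > 0) plant_group(n_uq, config$frac_unique_in_promoter_casteB, "promoter")
  dif <- if (n_diff > 0) plant_group(n_diff, config$frac_differential_in_promoter,
                                     "promoter")

  mk <- function(d, class, prefix) {
    if (is.null(d)) return(NULL)
    d$class <- class
    d$peak_id <- sprintf("%s_%04d", prefix, seq_len(nrow(d)))
    d
  }
  planted <- rbind(mk(bg, "background", "bg"),
                   mk(uqA, "unique_A", "uqA"),
                   mk(uqB, "unique_B", "uqB"),
                   mk(dif, "differential", "dif"))
  if (is.null(planted) || !nrow(planted)) {
    planted <- data.frame(mid = integer(), gene_id = character(),
                          feature = character(), class = character(),
                          peak_id = character())
  }

  # planted log2 fold changes (caste A over caste B): differential peaks
  # get signed magnitudes around planted_log2fc, signs split evenly
  planted$log2_fold_change <- rep(0, nrow(planted))
  di <- which(planted$class == "differential")
  if (length(di)) {
    sgn <- rep(c(1, -1), length.out = length(di))
    mag <- config$planted_log2fc * stats::runif(length(di), 0.8, 1.2)
    planted$log2_fold_change[di] <- sgn * mag
    planted$class[di] <- ifelse(sgn > 0, "differential_up_A", "differential_up_B")
  }
  planted$start <- planted$mid - hw
  planted$end <- planted$mid + hw
  planted$chrom <- rep(if (nrow(genome$chromosomes)) genome$chromosomes$name[1]
                       else "chrS", nrow(planted))

  # per-caste NB means
  m <- config$peak_mean_count
  mu_A <- ifelse(planted$class == "unique_B", NA_real_,
                 m * 2^(planted$log2_fold_change / 2))
  mu_B <- ifelse(planted$class == "unique_A", NA_real_,
                 m * 2^(-planted$log2_fold_change / 2))

  castes <- c("Q", "W")  # Q = caste A, W = caste B
  reps <- seq_len(config$n_replicates)
  rows <- list()
  for (ci in 1:2) {
    mu <- if (ci == 1) mu_A else mu_B
    own_unique <- planted$class == (if (ci == 1) "unique_A" else "unique_B")
    for (r in reps) {
      present <- !is.na(mu)
      if (config$dropout_prob > 0 && any(own_unique)) {
        drop <- stats::runif(sum(own_unique)) < config$dropout_prob
        present[which(own_unique)[drop]] <- FALSE
      }
      idx <- which(present)
      if (!length(idx)) next
      jit <- sample.int(2L * PEAK_JITTER + 1L, length(idx), replace = TRUE) -
        PEAK_JITTER - 1L
      count <- rnbinom_mu(length(idx), mu[idx], config$nb_dispersion)
      rows[[length(rows) + 1L]] <- data.frame(
        caste = castes[ci], replicate = r, chrom = planted$chrom[idx],
        start = planted$start[idx] + jit, end = planted$end[idx] + jit,
        name = planted$peak_id[idx], score = count,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(caste = character(), replicate = integer(), chrom = character(),
               start = integer(), end = integer(), name = character(),
               score = numeric())
  }
  peaks <- peaks[order(peaks$caste, peaks$replicate, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL

  truth_peaks <- planted[, c("peak_id", "chrom", "start", "end", "mid", "class",
                             "feature", "gene_id", "log2_fold_change")]
  rownames(truth_peaks) <- NULL
  truth <- structure(list(peaks = truth_peaks, genes = NULL,
                          params = unclass(config),
                          class_counts = as.list(table(truth_peaks$class))),
                     class = "truth_manifest")
  list(peaks = peaks, truth = truth)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("truth_manifest:\n  planted peaks:\n")
  if (nrow(x$peaks)) print(table(x$peaks$class)) else cat("    none\n")
  if (!is.null(x$genes)) {
    cat(sprintf("  genes: %d (%d planted DE, %d peak-linked)\n",
                nrow(x$genes), sum(x$genes$de), sum(!is.na(x$genes$linked_peak))))
  }
  invisible(x)
}

#' Write / read a truth manifest as JSON
#'
#' @param truth a `truth_manifest` from the simulator.
#' @param path output path.
#' @return `path` invisibly, or the manifest for the reader.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$genes) && !nrow(as.data.frame(x$genes))) x$genes <- NULL
  structure(x, class = "truth_manifest")
}

#' Mean score-weighted coverage of one caste's replicate peaks
#'
#' Builds a bedGraph-style track of read pile-up, averaged over that
#' caste's replicates. Read density within each called peak is modelled
#' as a symmetric triangular pile-up around the peak summit (reads
#' concentrate at the centre of a ChIP enrichment domain, not uniformly
#' across it), discretized in `step`-bp bands so the track stays compact.
#' Used as the signal input for [tss_metaprofile()].
#'
#' @param peaks long replicate peak data.frame (see [simulate_peaks()]).
#' @param caste caste label to select.
#' @param chrom_length chromosome length in bases.
#' @param step discretization band width in bases (default 50).
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
peak_coverage <- function(peaks, caste, chrom_length, step = 50L) {
  p <- peaks[peaks$caste == caste, , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric()))
  }
  n_rep <- length(unique(p$replicate))
  out <- list()
  for (ch in sort(unique(p$chrom))) {
    q <- p[p$chrom == ch, , drop = FALSE]
    # expand each peak into triangular bands: band k of n has relative
    # height 1 - |center_k - summit| / half_width
    bands <- lapply(seq_len(nrow(q)), function(i) {
      s <- q$start[i]; e <- q$end[i]
      edges <- unique(c(seq(s, e, by = step), e))
      bs <- edges[-length(edges)]
      be <- edges[-1]
      summit <- (s + e) / 2
      h <- pmax(0, 1 - abs((bs + be) / 2 - summit) / ((e - s) / 2))
      data.frame(start = bs, end = be, w = h * q$score[i] / n_rep)
    })
    bands <- do.call(rbind, bands)
    cov <- IRanges::coverage(IRanges::IRanges(bands$start + 1L, bands$end),
                             weight = bands$w,
                             width = as.integer(chrom_length))
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    starts <- ends - rl
    keep <- rv != 0
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                            value = rv[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
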