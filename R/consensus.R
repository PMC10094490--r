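# Consensus peak construction across castes and replicates.

#' Build consensus peaks across all replicates of both castes
#'
#' Takes the union of all replicate intervals and merges any that overlap
#' by at least 1 bp (book-ended intervals stay separate). For each
#' consensus interval, a replicate is flagged present when at least one of
#' its peaks overlaps it by >= 1 bp, and that replicate's signal is the sum
#' of the scores of its overlapping peaks (0 when absent).
#'
#' @param peaks long data.frame of replicate peak calls with columns
#'   `caste`, `replicate`, `chrom`, `start`, `end`, `score` (canonical
#'   0-based half-open, e.g. from [read_bed()]).
#' @param samples optional data.frame with columns `caste`, `replicate`
#'   enumerating the full design; defaults to the combinations observed in
#'   `peaks`. Supply it explicitly when a replicate may have zero peaks.
#' @return an object of class `consensus_peaks`: a list with `peaks`
#'   (data.frame `peak_id`, `chrom`, `start`, `end`, `midpoint`),
#'   logical `presence` and numeric `signal` matrices (peaks x samples),
#'   and the `samples` data.frame (with `sample_id` column).
#' @export
build_consensus <- function(peaks, samples = NULL) {
  if (is.null(samples)) {
    samples <- unique(peaks[, c("caste", "replicate")])
    samples <- samples[order(samples$caste, samples$replicate), , drop = FALSE]
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$sample_id <- paste0(samples$caste, "_rep", samples$replicate)
  rownames(samples) <- NULL
  ns <- nrow(samples)

  if (!nrow(peaks)) {
    empty <- data.frame(peak_id = character(), chrom = character(),
                        start = integer(), end = integer(), midpoint = integer())
    return(structure(list(peaks = empty,
                          presence = matrix(FALSE, 0, ns,
                                            dimnames = list(NULL, samples$sample_id)),
                          signal = matrix(0, 0, ns,
                                          dimnames = list(NULL, samples$sample_id)),
                          samples = samples),
                     class = "consensus_peaks"))
  }

  cons_list <- list()
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(p$start + 1L, p$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    cons_list[[ch]] <- data.frame(chrom = ch,
                                  start = IRanges::start(merged) - 1L,
                                  end = IRanges::end(merged),
                                  stringsAsFactors = FALSE)
  }
  cons <- do.call(rbind, cons_list)
  rownames(cons) <- NULL
  np <- nrow(cons)
  cons$peak_id <- sprintf("peak_%05d", seq_len(np))
  cons$midpoint <- (cons$start + cons$end) %/% 2L

  presence <- matrix(FALSE, np, ns, dimnames = list(cons$peak_id, samples$sample_id))
  signal <- matrix(0, np, ns, dimnames = list(cons$peak_id, samples$sample_id))
  key <- paste0(peaks$caste, "_rep", peaks$replicate)
  for (j in seq_len(ns)) {
    p <- peaks[key == samples$sample_id[j], , drop = FALSE]
    if (!nrow(p)) next
    for (ch in unique(p$chrom)) {
      ci <- which(cons$chrom == ch)
      pi <- which(p$chrom == ch)
      if (!length(ci)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(p$start[pi] + 1L, p$end[pi]),
        IRanges::IRanges(cons$start[ci] + 1L, cons$end[ci]))
      if (!length(ov)) next
      sh <- ci[S4Vectors::subjectHits(ov)]
      presence[sh, j] <- TRUE
      sc <- p$score[pi[S4Vectors::queryHits(ov)]]
      sc[is.na(sc)] <- 0
      agg <- rowsum(sc, group = sh)
      signal[as.integer(rownames(agg)), j] <-
        signal[as.integer(rownames(agg)), j] + agg[, 1]
    }
  }
  structure(list(peaks = cons[, c("peak_id", "chrom", "start", "end", "midpoint")],
                 presence = presence, signal = signal, samples = samples),
            class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat(sprintf("consensus_peaks: %d peak(s) x %d sample(s) [%s]\n",
              nrow(x$peaks), nrow(x$samples),
              paste(x$samples$sample_id, collapse = ", ")))
  if (!is.null(x$peaks$class)) {
    print(table(x$peaks$class))
  }
  invisible(x)
}
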