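# Relative quantification of qPCR data by the 2^-ddCt method with
# reference-gene normalization, and group comparison by Welch's t-test on
# the dCt scale (the approximately normal scale; a flag switches to RQ).

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene) first. Then per
#' sample `dCt = Ct_target - Ct_reference`, per sample
#' `ddCt = dCt - mean(dCt over control-group samples)`, and
#' `RQ = 2^-ddCt`, so the control group's mean RQ has geometric mean 1.
#'
#' @param ct Ct table data.frame with columns `sample`, `group`, `gene`,
#'   `ct` (see [read_ct_table()]).
#' @param target target gene id.
#' @param reference reference (housekeeping) gene id, e.g. `"GAPDH"`.
#' @param control_group group label used as the ddCt baseline.
#' @return object of class `relative_expression`: list with `per_sample`
#'   (data.frame `sample`, `group`, `delta_ct`, `ddct`, `rq`), `summary`
#'   (per group: mean RQ, SEM, n), and the call parameters.
#' @export
delta_delta_ct <- function(ct, target, reference, control_group) {
  for (g in c(target, reference)) {
    if (!g %in% ct$gene) stopf("gene '%s' not present in the Ct table", g)
  }
  if (!control_group %in% ct$group) {
    stopf("control group '%s' not present in the Ct table", control_group)
  }
  agg <- stats::aggregate(ct ~ sample + group + gene, data = ct, FUN = mean)
  tgt <- agg[agg$gene == target, , drop = FALSE]
  ref <- agg[agg$gene == reference, , drop = FALSE]
  m <- match(tgt$sample, ref$sample)
  if (anyNA(m)) {
    stopf("reference gene '%s' missing for sample '%s'", reference,
          tgt$sample[which(is.na(m))[1]])
  }
  dct <- tgt$ct - ref$ct[m]
  ctrl <- tgt$group == control_group
  if (!any(ctrl)) stopf("no samples in control group '%s' measured for '%s'",
                        control_group, target)
  ddct <- dct - mean(dct[ctrl])
  per_sample <- data.frame(sample = tgt$sample, group = tgt$group,
                           delta_ct = dct, ddct = ddct, rq = 2^(-ddct),
                           stringsAsFactors = FALSE)
  per_sample <- per_sample[order(per_sample$group, per_sample$sample), ,
                           drop = FALSE]
  rownames(per_sample) <- NULL
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d), mean_rq = mean(d$rq),
               sem_rq = stats::sd(d$rq) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_sample = per_sample, summary = summ, target = target,
                 reference = reference, control_group = control_group),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression of '%s' (reference '%s', control '%s')\n",
              x$target, x$reference, x$control_group))
  print(x$summary)
  invisible(x)
}

#' Two-group comparison of qPCR relative expression
#'
#' Welch's two-sided t-test between groups, by default on the dCt scale
#' (where the noise is approximately normal); fold changes are still
#' reported as RQ by [delta_delta_ct()].
#'
#' @param x a [delta_delta_ct()] result, or a numeric vector of values.
#' @param groups group labels per value (ignored when `x` is a
#'   `relative_expression`, whose two groups are used).
#' @param scale `"delta_ct"` (default) or `"rq"`.
#' @return list with `t`, `df`, `p_value`, `groups`.
#' @export
group_ttest <- function(x, groups = NULL, scale = c("delta_ct", "rq")) {
  scale <- match.arg(scale)
  if (inherits(x, "relative_expression")) {
    groups <- x$per_sample$group
    x <- x$per_sample[[if (scale == "delta_ct") "delta_ct" else "rq"]]
  }
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups required")
  tab <- table(groups)
  if (any(tab < 2)) {
    stopf("group '%s' has fewer than 2 values", names(tab)[which(tab < 2)[1]])
  }
  a <- x[groups == levels(groups)[1]]
  b <- x[groups == levels(groups)[2]]
  if (stats::var(a) < 1e-12 && stats::var(b) < 1e-12) {
    eq <- abs(mean(a) - mean(b)) < 1e-12
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p_value = if (eq) 1 else 0,
                groups = levels(groups)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, groups = levels(groups))
}
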