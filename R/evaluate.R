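# Scoring discovery lists against simulation truth, p-value calibration,
# the CPM filter, and per-gene residual diagnostics.

#' Confusion metrics at discovery thresholds
#'
#' A discovery is `p_adj <= threshold`. Observed FDR is false discoveries
#' over discoveries (0 when there are none), sensitivity is true
#' discoveries over the number of truly DE genes, and the type-I error is
#' the fraction of null genes with raw p-value at or below the nominal
#' level (the same threshold).
#'
#' @param p_adj BH-adjusted p-values (NA = not tested, never discovered).
#' @param truth Logical vector (or truth table with `is_de`) marking truly
#'   DE genes.
#' @param thresholds Numeric vector of thresholds to evaluate.
#' @param p_raw Optional raw p-values for the type-I error column.
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_discoveries`, `observed_fdr`, `sensitivity`, `type1_error`,
#'   `n_datasets` (always 1; see [average_metrics()]).
#' @export
confusion_metrics <- function(p_adj, truth, thresholds = 0.05,
                              p_raw = NULL) {
  if (is.data.frame(truth)) truth <- truth$is_de
  truth <- as.logical(truth)
  if (length(p_adj) != length(truth))
    stop("p_adj and truth must have equal length")
  if (!is.null(p_raw) && length(p_raw) != length(truth))
    stop("p_raw and truth must have equal length")
  n_true <- sum(truth)
  rows <- lapply(thresholds, function(th) {
    disc <- !is.na(p_adj) & p_adj <= th
    nd <- sum(disc)
    fd <- sum(disc & !truth)
    td <- sum(disc & truth)
    t1 <- if (!is.null(p_raw)) {
      nulls <- !truth & !is.na(p_raw)
      if (any(nulls)) mean(p_raw[nulls] <= th) else NA_real_
    } else NA_real_
    data.frame(threshold = th, n_discoveries = nd,
               observed_fdr = if (nd > 0) fd / nd else 0,
               sensitivity = if (n_true > 0) td / n_true else NA_real_,
               type1_error = t1, n_datasets = 1L)
  })
  do.call(rbind, rows)
}

#' Average confusion metrics over datasets
#'
#' Row-binds per-dataset summaries (matched on threshold) and averages the
#' metric columns; `n_datasets` records how many summaries entered each
#' average.
#'
#' @param summaries List of [confusion_metrics()] outputs.
#' @return data.frame in the same layout.
#' @export
average_metrics <- function(summaries) {
  all <- do.call(rbind, summaries)
  out <- do.call(rbind, lapply(split(all, all$threshold), function(d) {
    data.frame(threshold = d$threshold[1],
               n_discoveries = mean(d$n_discoveries),
               observed_fdr = mean(d$observed_fdr),
               sensitivity = mean(d$sensitivity),
               type1_error = mean(d$type1_error),
               n_datasets = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$threshold), , drop = FALSE]
}

#' P-value calibration against the uniform distribution
#'
#' One-sample Kolmogorov-Smirnov distance of the supplied (null) p-values
#' from Uniform(0, 1), plus 20-bin histogram counts for plotting.
#'
#' @param p Raw p-values of null genes (at least 100, no NA).
#' @param n_bins Number of histogram bins.
#' @return List with `ks_distance`, `ks_p`, `bin_counts`, `breaks`.
#' @export
pvalue_calibration <- function(p, n_bins = 20) {
  p <- p[!is.na(p)]
  if (length(p) < 100)
    stop("at least 100 null p-values are required")
  ks <- suppressWarnings(ks.test(p, "punif"))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  cnt <- table(cut(p, breaks, include.lowest = TRUE))
  list(ks_distance = unname(ks$statistic), ks_p = unname(ks$p.value),
       bin_counts = as.vector(cnt), breaks = breaks)
}

#' Counts-per-million expression filter
#'
#' Keeps genes with at least `min_cpm` counts per million (relative to the
#' per-sample library size) in at least `min_samples` samples, the usual
#' pre-filter before model fitting.
#'
#' @param counts Count matrix.
#' @param min_cpm CPM threshold.
#' @param min_samples Minimum number of samples meeting the threshold
#'   (0 = keep everything).
#' @return List with `counts` (filtered matrix) and `kept` (logical vector
#'   over the input genes).
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples) {
  counts <- as_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  kept <- rowSums(cpm >= min_cpm) >= min_samples
  list(counts = counts[kept, , drop = FALSE], kept = kept)
}

#' Residual diagnostics for one gene's fit
#'
#' Brown-Forsythe (median-centered Levene) test for equality of the
#' conditional-residual variances between time points, and a
#' Kolmogorov-Smirnov test of the scaled residuals against the standard
#' normal. Scaled residuals are conditional residuals divided by their
#' model-implied standard deviations.
#'
#' @param fit A `"seqlmm_fit"`.
#' @param time Per-observation time/occasion labels (same order as the
#'   data the gene was fit on).
#' @return data.frame with `levene_p` (NA when any time group has fewer
#'   than 2 observations) and `ks_normality_p`.
#' @export
residual_diagnostics <- function(fit, time) {
  stopifnot(inherits(fit, "seqlmm_fit"))
  if (!fit$estimable || !fit$converged)
    stop("residual diagnostics require a converged fit")
  r <- fit$resid_conditional
  g <- factor(time)
  if (length(r) != length(g))
    stop("time labels must match the number of observations")
  lev_p <- if (any(table(g) < 2)) NA_real_ else {
    z <- abs(r - tapply(r, g, median)[g])
    anova(lm(z ~ g))[["Pr(>F)"]][1]
  }
  ks_p <- suppressWarnings(ks.test(fit$resid_scaled, "pnorm")$p.value)
  data.frame(levene_p = lev_p, ks_normality_p = ks_p)
}
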