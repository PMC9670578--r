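#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over a reference set of
#' genes with all-positive counts, of the ratio of each sample's count to the
#' gene's geometric mean across samples. The factors are invariant to gene
#' order and scale-equivariant up to a common rescaling: doubling one
#' library doubles its factor relative to every other factor (the per-gene
#' geometric means absorb a factor `2^(1/n)` shared by all samples).
#'
#' @param counts Count matrix (genes x samples), see [as_count_matrix()].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has all-positive counts; filter low-count genes or add a ",
         "pseudo-count before estimating size factors")
  log_geo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2,
              function(cnt) exp(median(log(cnt) - log_geo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor estimation failed (non-positive factor)")
  sf
}

#' Gene-wise negative-binomial dispersion estimates
#'
#' For each gene, fits a mean model (Poisson GLM with `log(size factor)`
#' offset and the supplied fixed-effects design over samples) and then
#' maximizes the negative-binomial likelihood over the dispersion `alpha`
#' with the fitted means held fixed, under the convention
#' `Var(C) = mu + alpha * mu^2`. Estimates are bounded to
#' `[alpha_min, alpha_max]`; genes with all-zero counts are flagged and get
#' `NA`. Repeated-measures structure is deliberately ignored at this stage
#' (the trend only needs a coarse location for each gene's dispersion).
#'
#' @param counts Count matrix.
#' @param size_factors Output of [estimate_size_factors()].
#' @param design Optional numeric design matrix over samples for the mean
#'   model; defaults to intercept-only.
#' @param alpha_min,alpha_max Bounds on the dispersion estimate.
#' @return A data.frame with one row per gene: `gene`, `base_mean` (mean of
#'   normalized counts), `dispersion`, and flags `all_zero`, `at_bound`,
#'   `converged`.
#' @export
estimate_dispersions <- function(counts, size_factors, design = NULL,
                                 alpha_min = 1e-8, alpha_max = 10) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2) stop("at least 2 samples are required")
  if (length(size_factors) != ncol(counts))
    stop("size_factors length must equal the number of samples")
  if (is.null(design)) design <- matrix(1, ncol(counts), 1)
  design <- as.matrix(design)
  off <- log(size_factors)
  n_genes <- nrow(counts)
  disp <- rep(NA_real_, n_genes)
  at_bound <- conv <- rep(FALSE, n_genes)
  all_zero <- rowSums(counts) == 0
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  lb <- log(alpha_min); ub <- log(alpha_max)
  for (g in which(!all_zero)) {
    y <- counts[g, ]
    mu <- tryCatch({
      f <- suppressWarnings(
        glm.fit(design, y, family = poisson(), offset = off))
      pmax(f$fitted.values, 1e-8)
    }, error = function(e) pmax(base_mean[g] * size_factors, 1e-8))
    nll <- function(la) -sum(dnbinom(y, mu = mu, size = exp(-la), log = TRUE))
    res <- tryCatch(optimize(nll, c(lb, ub), tol = 1e-8),
                    error = function(e) NULL)
    if (is.null(res)) {
      disp[g] <- alpha_max
      at_bound[g] <- TRUE
      next
    }
    # optimize() never returns the endpoints; compare explicitly
    cand <- c(res$minimum, lb, ub)
    vals <- c(res$objective, nll(lb), nll(ub))
    la_hat <- cand[which.min(vals)]
    disp[g] <- exp(la_hat)
    at_bound[g] <- la_hat <= lb + 1e-6 || la_hat >= ub - 1e-6
    conv[g] <- TRUE
  }
  data.frame(gene = rownames(counts), base_mean = base_mean,
             dispersion = disp, all_zero = all_zero, at_bound = at_bound,
             converged = conv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the parametric mean-dispersion trend alpha(mu) = a0 + a1 / mu
#'
#' Gamma-family regression (identity link) of gene-wise dispersions on the
#' reciprocal of their fitted means, iteratively refit after excluding genes
#' whose ratio of observed to fitted dispersion falls outside
#' `ratio_window`, until the coefficients change by less than `tol` or
#' `max_iter` iterations. `a0` is the asymptotic (high-count) dispersion and
#' `a1` the extra-Poisson term; both must be non-negative with `a0 > 0` for
#' the closed-form VST to exist. If the fit degenerates (`a0 <= 0` or the
#' GLM fails) the trend falls back to a flat `a0 = median(dispersion)` with
#' a warning.
#'
#' @param means Per-gene means of normalized counts.
#' @param dispersions Per-gene dispersion estimates.
#' @param ratio_window Keep genes with `dispersion / fitted` inside this
#'   interval when iterating.
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Iteration cap.
#' @return An object of class `"dispersion_trend"`: list with `a0`, `a1`,
#'   `iterations`, `n_used`, and the `means`/`dispersions` retained for audit.
#' @export
fit_dispersion_trend <- function(means, dispersions,
                                 ratio_window = c(1e-4, 15),
                                 tol = 1e-6, max_iter = 10) {
  ok <- is.finite(means) & means > 0 & is.finite(dispersions) & dispersions > 0
  if (sum(ok) < 10)
    stop("need at least 10 genes with positive mean and finite dispersion")
  mu <- means[ok]; a <- dispersions[ok]
  fallback <- function() {
    warning("dispersion trend fit degenerate; falling back to a flat trend ",
            "a0 = median(dispersion), a1 = 0")
    structure(list(a0 = median(a), a1 = 0, iterations = 0L,
                   n_used = length(a), means = means,
                   dispersions = dispersions),
              class = "dispersion_trend")
  }
  keep <- rep(TRUE, length(a))
  co <- c(median(a), 0)
  it <- 0L
  repeat {
    it <- it + 1L
    fit <- tryCatch(
      suppressWarnings(glm(a[keep] ~ I(1 / mu[keep]),
                           family = Gamma(link = "identity"),
                           start = pmax(co, c(1e-4, 0)))),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback())
    new_co <- unname(coef(fit))
    fitted_all <- new_co[1] + new_co[2] / mu
    delta <- max(abs(new_co - co))
    co <- new_co
    if (co[1] <= 0 || any(!is.finite(co))) return(fallback())
    ratio <- a / pmax(fitted_all, 1e-12)
    keep <- ratio >= ratio_window[1] & ratio <= ratio_window[2]
    if (sum(keep) < 10) return(fallback())
    if (delta < tol || it >= max_iter) break
  }
  a1 <- max(co[2], 0)
  structure(list(a0 = co[1], a1 = a1, iterations = it, n_used = sum(keep),
                 means = means, dispersions = dispersions),
            class = "dispersion_trend")
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("Dispersion trend alpha(mu) = %.6g + %.6g/mu (fit on %d genes, %d iterations)\n",
              x$a0, x$a1, x$n_used, x$iterations))
  invisible(x)
}

# Closed form of the variance-stabilizing integral
#   u(q) = (1/ln 2) * \int dmu / sqrt((1 + a1) mu + a0 mu^2)  (+ constant)
# anchored so that u(q) ~ log2(q) for large q.
.vst_closed_form <- function(q, a0, a1) {
  log2(2 * a0 * q + (1 + a1) + 2 * sqrt(a0 * q * (a0 * q + 1 + a1))) -
    log2(4 * a0)
}

#' Variance-stabilizing transformation of a count matrix
#'
#' Applies the closed form of `integral( dmu / sqrt(v(mu)) )` for the
#' negative-binomial variance implied by the dispersion trend,
#' `v(mu) = (1 + a1) * mu + a0 * mu^2`, to size-factor-normalized counts,
#' rescaled so values are approximately on the log2 scale for large counts.
#' The transform is monotone in the normalized count and finite at zero; no
#' pseudo-counts are added. An optional matrix of per-observation precision
#' weights is carried through untouched (identity weights by default) for
#' use by downstream model fitting.
#'
#' @param counts Count matrix.
#' @param size_factors Per-sample size factors.
#' @param trend A `"dispersion_trend"` object (or list with `a0`, `a1`).
#' @param weights Optional positive matrix of the same dimension.
#' @return Numeric matrix of transformed values with the same dimnames;
#'   weights (if supplied) attached as `attr(, "weights")`.
#' @export
vst_transform <- function(counts, size_factors, trend, weights = NULL) {
  counts <- as_count_matrix(counts)
  if (length(size_factors) != ncol(counts))
    stop("size_factors length must equal the number of samples")
  if (is.null(trend$a0) || trend$a0 <= 0)
    stop("invalid dispersion trend: a0 must be positive")
  q <- sweep(counts, 2, size_factors, "/")
  v <- .vst_closed_form(q, trend$a0, trend$a1)
  if (any(!is.finite(v))) stop("non-finite transformed values produced")
  dimnames(v) <- dimnames(counts)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(counts)))
      stop("weights must have the same dimensions as counts")
    if (any(weights <= 0)) stop("weights must be positive")
    attr(v, "weights") <- weights
  }
  v
}

#' One-call VST pipeline
#'
#' Convenience wrapper running [estimate_size_factors()],
#' [estimate_dispersions()], [fit_dispersion_trend()], and
#' [vst_transform()].
#'
#' @param counts Count matrix.
#' @param design Optional sample-level design matrix for the dispersion mean
#'   model.
#' @param weights Optional precision-weight matrix, carried through.
#' @return List with `transformed`, `size_factors`, `trend`, `dispersions`.
#' @export
vst <- function(counts, design = NULL, weights = NULL) {
  counts <- as_count_matrix(counts)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, design = design)
  trend <- fit_dispersion_trend(disp$base_mean, disp$dispersion)
  list(transformed = vst_transform(counts, sf, trend, weights = weights),
       size_factors = sf, trend = trend, dispersions = disp)
}
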