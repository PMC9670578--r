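# Satterthwaite-degree-of-freedom inference on REML fits.

#' Satterthwaite denominator degrees of freedom for a 1-df contrast
#'
#' Moment-matching df for the Wald t statistic of `c' beta`:
#' `df = 2 (c' Vb c)^2 / (g' A g)` where `Vb` is the fixed-effect
#' covariance at the estimated covariance parameters, `g` the gradient of
#' `c' Vb(theta) c` with respect to the covariance parameters (central
#' finite differences, precomputed at fit time), and `A` the asymptotic
#' covariance of the covariance-parameter estimates. The same formula
#' applies to random-effects and marginal (CS/UN) fits. A non-positive
#' denominator falls back to the residual df `n - rank(X)` with a warning.
#'
#' @param fit A `"seqlmm_fit"`.
#' @param contrast Numeric contrast vector of length `p`.
#' @return The estimated degrees of freedom (positive scalar).
#' @export
satterthwaite_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "seqlmm_fit"))
  if (!fit$estimable) return(NA_real_)
  cvec <- as.numeric(contrast)
  if (length(cvec) != length(fit$beta))
    stop("contrast length must equal the number of coefficients")
  vc <- drop(cvec %*% fit$vcov_beta %*% cvec)
  k <- dim(fit$dVb)[3]
  g <- vapply(seq_len(k),
              function(j) drop(cvec %*% fit$dVb[, , j] %*% cvec), 0)
  den <- drop(t(g) %*% fit$A %*% g)
  if (!is.finite(den) || den <= 0) {
    warning("non-positive Satterthwaite denominator; using residual df")
    return(fit$df_residual)
  }
  df <- 2 * vc^2 / den
  if (!is.finite(df) || df <= 0) {
    warning("degenerate Satterthwaite df; using residual df")
    return(fit$df_residual)
  }
  df
}

#' t-test of a single contrast
#'
#' Wald t statistic `c' beta / sqrt(c' Vb c)` referred to a t distribution
#' with Satterthwaite degrees of freedom; two-sided p-value.
#'
#' @param fit A `"seqlmm_fit"`.
#' @param contrast Numeric contrast vector (length `p`), or a 1-row matrix.
#' @return One-row data.frame: `estimate`, `se`, `df`, `statistic`,
#'   `p_value`, `singular`, `converged`.
#' @export
t_test_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "seqlmm_fit"))
  cvec <- as.numeric(contrast)
  out <- data.frame(estimate = NA_real_, se = NA_real_, df = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    singular = isTRUE(fit$singular),
                    converged = isTRUE(fit$converged) && isTRUE(fit$estimable))
  if (!fit$estimable) return(out)
  if (all(cvec == 0)) stop("contrast must not be all zero")
  est <- drop(cvec %*% fit$beta)
  v <- drop(cvec %*% fit$vcov_beta %*% cvec)
  if (!is.finite(v) || v <= 0) {
    out$converged <- FALSE
    return(out)
  }
  se <- sqrt(v)
  df <- satterthwaite_df(fit, cvec)
  stat <- est / se
  out$estimate <- est; out$se <- se; out$df <- df; out$statistic <- stat
  out$p_value <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  out
}

#' F-test of a multi-row contrast
#'
#' Wald quadratic form `(L beta)' (L Vb L')^{-1} (L beta) / r` with the
#' denominator df from the eigendecomposition approach: each eigendirection
#' of `L Vb L'` is treated as a 1-df contrast with its own Satterthwaite
#' df `nu_i`, and the directions are moment-matched into a single
#' denominator df `2 E / (E - r)` with `E = sum(nu_i / (nu_i - 2))` over
#' directions with `nu_i > 2`. For `r = 1` this reduces exactly to the
#' squared t-test.
#'
#' @param fit A `"seqlmm_fit"`.
#' @param L Contrast matrix (r x p), full row rank.
#' @return One-row data.frame: `statistic` (F), `df1`, `df` (denominator),
#'   `p_value`, `singular`, `converged`.
#' @export
f_test_contrasts <- function(fit, L) {
  stopifnot(inherits(fit, "seqlmm_fit"))
  L <- rbind(L)
  r <- nrow(L)
  out <- data.frame(statistic = NA_real_, df1 = r, df = NA_real_,
                    p_value = NA_real_, singular = isTRUE(fit$singular),
                    converged = isTRUE(fit$converged) && isTRUE(fit$estimable))
  if (!fit$estimable) return(out)
  rnk <- qr(L)$rank
  if (rnk < r)
    stop("contrast matrix is rank deficient (", r - rnk,
         " dependent row(s) among rows ",
         paste(rownames(L) %||% seq_len(r), collapse = ", "), ")")
  Vc <- L %*% fit$vcov_beta %*% t(L)
  e <- eigen((Vc + t(Vc)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) {
    out$converged <- FALSE
    return(out)
  }
  P <- t(e$vectors) %*% L            # r x p, rows are eigendirection contrasts
  tstats2 <- (as.vector(P %*% fit$beta))^2 / e$values
  Fstat <- sum(tstats2) / r
  nu <- vapply(seq_len(r), function(i) satterthwaite_df(fit, P[i, ]), 0)
  ok <- is.finite(nu) & nu > 2
  if (!any(ok)) {
    warning("all eigendirection dfs <= 2; F-test p-value unavailable")
    out$statistic <- Fstat
    return(out)
  }
  E <- sum(nu[ok] / (nu[ok] - 2))
  den_df <- if (E > r) 2 * E / (E - r) else Inf
  out$statistic <- Fstat
  out$df <- den_df
  out$p_value <- pf(Fstat, r, den_df, lower.tail = FALSE)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment with missing values propagated: `NA` entries are
#' excluded from the number of tests `m` and returned as `NA`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Build a contrast from the fitted design
#'
#' Named helpers construct contrast rows by evaluating the fixed-effects
#' design at synthetic covariate settings, so they work for both continuous
#' and categorical time codings:
#' * `"coef"`: unit contrast selecting a named coefficient.
#' * `"between_at_time"`: non-reference group minus reference group at time
#'   `value` (the between-subject test; with continuous time 0..3 and
#'   `value = 3` this selects `beta1 + 3 * beta3`).
#' * `"within_change"`: change over time within group `value` (per unit of
#'   time for continuous coding; last versus first occasion for categorical
#'   coding).
#' * `"interaction"`: the group-by-time interaction coefficients; a single
#'   row for continuous time, one row per follow-up occasion (a joint
#'   F-test) for categorical time.
#'
#' @param design An `"lmm_design"` (or `"seqlmm_fits"` object).
#' @param type Contrast type, see above.
#' @param value Coefficient name for `"coef"`; time value for
#'   `"between_at_time"`; group level for `"within_change"`.
#' @param group_var,time_var Names of the group and time covariates.
#' @return A contrast matrix (rows x p) with labelled rows.
#' @export
make_contrast <- function(design, type = c("coef", "between_at_time",
                                           "within_change", "interaction"),
                          value = NULL, group_var = "group",
                          time_var = "time") {
  if (inherits(design, "seqlmm_fits")) design <- design$design
  stopifnot(inherits(design, "lmm_design"))
  type <- match.arg(type)
  cn <- colnames(design$X)
  p <- length(cn)
  if (type == "coef") {
    if (!value %in% cn)
      stop("unknown coefficient '", value, "'; available: ",
           paste(cn, collapse = ", "))
    L <- matrix(0, 1, p, dimnames = list(value, cn))
    L[1, value] <- 1
    return(L)
  }
  md <- design$metadata
  for (v in c(group_var, time_var))
    if (!v %in% colnames(md))
      stop("variable '", v, "' not found in the metadata")
  grp <- md[[group_var]]
  if (!is.factor(grp)) grp <- factor(grp)
  if (nlevels(grp) != 2)
    stop("contrast helpers require a two-level group variable")
  tv <- md[[time_var]]
  t_cat <- is.factor(tv)
  times <- if (t_cat) levels(tv) else sort(unique(tv))
  row_at <- function(g, t) {
    nd <- md[1, , drop = FALSE]
    nd[[group_var]] <- factor(g, levels = levels(grp))
    nd[[time_var]] <- if (t_cat) factor(t, levels = times) else t
    model.matrix(design$terms, nd, xlev = design$xlev)[1, ]
  }
  if (type == "between_at_time") {
    tval <- if (is.null(value)) times[length(times)] else value
    L <- rbind(row_at(levels(grp)[2], tval) - row_at(levels(grp)[1], tval))
    rownames(L) <- paste0("between_at_time:", tval)
    return(L)
  }
  if (type == "within_change") {
    gval <- if (is.null(value)) levels(grp)[2] else value
    if (!gval %in% levels(grp)) stop("unknown group level '", gval, "'")
    if (t_cat) {
      L <- rbind(row_at(gval, times[length(times)]) - row_at(gval, times[1]))
      rownames(L) <- paste0("within_change:", gval)
    } else {
      # per-unit-time slope within the group
      t0 <- times[1]
      L <- rbind(row_at(gval, t0 + 1) - row_at(gval, t0))
      rownames(L) <- paste0("within_change:", gval)
    }
    return(L)
  }
  # interaction: all group:time interaction columns
  ix <- grepl(":", cn) & grepl(group_var, cn) & grepl(time_var, cn)
  if (!any(ix))
    stop("no group-by-time interaction columns found in the design")
  L <- matrix(0, sum(ix), p, dimnames = list(cn[ix], cn))
  L[cbind(seq_len(sum(ix)), which(ix))] <- 1
  L
}

#' Results table for a contrast across all genes
#'
#' Applies [t_test_contrast()] (single-row contrast) or
#' [f_test_contrasts()] (multi-row) to every gene, then BH-adjusts the raw
#' p-values. With `exclude_singular = TRUE`, genes flagged as singular fits
#' are dropped before adjustment so the number of tests reflects only the
#' genes actually tested; the number excluded is reported as an attribute.
#' Genes whose fit failed to converge get missing p-values and never enter
#' the adjustment.
#'
#' @param fits A `"seqlmm_fits"` object.
#' @param contrast A contrast vector/matrix, or the output of
#'   [make_contrast()].
#' @param exclude_singular Drop singular fits from the table (and from the
#'   BH family) instead of flagging them.
#' @param sort_by_p Stable-sort rows by raw p-value (ties keep input gene
#'   order).
#' @return data.frame with columns `gene`, `estimate`, `se`, `df`,
#'   `statistic`, `p_value`, `p_adj`, `singular`, `converged`; attribute
#'   `n_excluded_singular`.
#' @export
summarize_results <- function(fits, contrast, exclude_singular = TRUE,
                              sort_by_p = FALSE) {
  stopifnot(inherits(fits, "seqlmm_fits"))
  L <- rbind(contrast)
  single <- nrow(L) == 1
  rows <- lapply(fits$fits, function(f) {
    if (single) t_test_contrast(f, L[1, ]) else f_test_contrasts(f, L)
  })
  tab <- do.call(rbind, rows)
  if (!single) {
    tab$estimate <- NA_real_
    tab$se <- NA_real_
    tab <- tab[, c("estimate", "se", "df", "statistic", "p_value",
                   "singular", "converged", "df1")]
  }
  tab <- data.frame(gene = fits$genes, tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  n_singular <- sum(tab$singular, na.rm = TRUE)
  if (exclude_singular && n_singular > 0)
    tab <- tab[!tab$singular, , drop = FALSE]
  tab$p_value[!tab$converged] <- NA_real_
  tab$p_adj <- bh_adjust(tab$p_value)
  cols <- c("gene", "estimate", "se", "df", "statistic", "p_value", "p_adj",
            "singular", "converged")
  if (!single) cols <- append(cols, "df1", after = 3)
  tab <- tab[, cols]
  if (sort_by_p) {
    ord <- order(tab$p_value, seq_len(nrow(tab)), na.last = TRUE)
    tab <- tab[ord, , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "n_excluded_singular") <- if (exclude_singular) n_singular else 0L
  tab
}

#' Write a results table as TSV
#'
#' Fixed header `gene, estimate, se, df, statistic, p_value, p_adj,
#' singular, converged`, preceded by `#` comment lines recording
#' provenance.
#'
#' @param tab Results table from [summarize_results()].
#' @param path Output path.
#' @param header_lines Extra comment lines (seed, config hash, ...).
#' @export
write_results <- function(tab, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hl <- c(paste0("seqlmm version ", as.character(packageVersion("seqlmm"))),
          header_lines)
  writeLines(paste0("# ", hl), con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
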