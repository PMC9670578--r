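#' Specify the per-gene linear mixed model
#'
#' Declares the fixed-effect formula and exactly one mechanism for
#' within-subject correlation: subject-level random effects (random
#' intercept, or random intercept + slope on a continuous time variable), or
#' a marginal residual covariance structure (compound symmetric or
#' unstructured over a categorical occasion variable). The two mechanisms
#' are mutually exclusive, mirroring the two fitting backends.
#'
#' @param fixed Fixed-effects formula over metadata columns, e.g.
#'   `~ group * time`.
#' @param random One of `"none"`, `"intercept"`, `"intercept_slope"`.
#' @param structure One of `"independent"`, `"cs"`, `"un"`.
#' @param subject Name of the metadata column identifying subjects.
#' @param time Name of the time/occasion column; required for
#'   `random = "intercept_slope"` (continuous slope variable) and for
#'   `structure = "un"` (categorical occasion index), used for occasion
#'   ordering under `"cs"` when present.
#' @param weights Name of an optional metadata column of positive
#'   per-observation weights, entering the model as residual variance
#'   `sigma^2 / w`.
#' @param reference Named list mapping factor covariates to their reference
#'   level; unlisted factors use the first level in sorted order.
#' @param singular_tol Relative tolerance for declaring a fit singular: a
#'   random-effect variance below `singular_tol` times the total variance
#'   (or a correlation at its boundary) flags the fit.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(fixed, random = c("none", "intercept", "intercept_slope"),
                       structure = c("independent", "cs", "un"),
                       subject = "subject", time = NULL, weights = NULL,
                       reference = NULL, singular_tol = 1e-4) {
  random <- match.arg(random)
  structure <- match.arg(structure)
  if (!inherits(fixed, "formula")) stop("fixed must be a formula")
  has_re <- random != "none"
  has_cov <- structure != "independent"
  if (has_re == has_cov)
    stop("specify exactly one correlation mechanism: random effects ",
         "(random != 'none') or a residual covariance structure ",
         "(structure != 'independent')")
  if (random == "intercept_slope" && is.null(time))
    stop("random = 'intercept_slope' requires a time variable")
  if (structure == "un" && is.null(time))
    stop("structure = 'un' requires a categorical occasion (time) variable")
  structure(list(fixed = fixed, random = random, structure = structure,
                 subject = subject, time = time, weights = weights,
                 reference = reference, singular_tol = singular_tol),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Linear mixed model specification\n")
  cat("  fixed:    ", deparse(x$fixed), "\n")
  if (x$random != "none")
    cat("  random:   ", x$random, "by", x$subject, "\n")
  else
    cat("  residual: ", x$structure, "within", x$subject, "\n")
  invisible(x)
}

#' Build design matrices from sample metadata
#'
#' Expands the fixed-effects formula against declared reference levels,
#' constructs the random-effects columns, and indexes observations by
#' subject (and occasion where the structure needs it). Column order is
#' deterministic; interaction columns follow the `a:b` naming of
#' [stats::model.matrix()].
#'
#' @param metadata Data.frame of per-sample covariates; must contain the
#'   subject column and every covariate named in the spec.
#' @param spec A [model_spec()].
#' @return A list of class `"lmm_design"` with elements `X`, `Z`, `subject`
#'   (factor), `occasion`, `weights`, dimensions, and bookkeeping used by
#'   the fitters.
#' @export
build_design <- function(metadata, spec) {
  stopifnot(inherits(spec, "model_spec"))
  metadata <- as.data.frame(metadata)
  vars <- all.vars(spec$fixed)
  needed <- unique(c(vars, spec$subject, spec$time, spec$weights))
  missing_vars <- setdiff(needed, colnames(metadata))
  if (length(missing_vars))
    stop("covariate(s) missing from metadata: ",
         paste(missing_vars, collapse = ", "))
  md <- metadata
  for (v in colnames(md)) {
    if (is.character(md[[v]]) || is.logical(md[[v]]))
      md[[v]] <- factor(md[[v]], levels = sort(unique(md[[v]])))
    if (is.factor(md[[v]])) {
      ref <- spec$reference[[v]]
      if (!is.null(ref)) {
        if (!ref %in% levels(md[[v]]))
          stop("reference level '", ref, "' not found in variable '", v, "'")
        md[[v]] <- stats::relevel(md[[v]], ref = ref)
      }
    }
  }
  subject <- factor(md[[spec$subject]])
  if (anyNA(subject)) stop("missing subject identifiers in metadata")
  if (any(table(subject) < 1)) stop("every subject needs >= 1 observation")

  trm <- terms(spec$fixed, data = md)
  X <- model.matrix(trm, md)
  xlev <- lapply(md[, intersect(vars, colnames(md)), drop = FALSE],
                 function(col) if (is.factor(col)) levels(col))
  xlev <- xlev[!vapply(xlev, is.null, TRUE)]
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("fixed-effects design is rank deficient (rank ", qrX$rank,
         " < ", p, " columns); drop collinear covariates")

  Z <- NULL
  if (spec$random == "intercept") {
    Z <- matrix(1, nrow(X), 1, dimnames = list(NULL, "(Intercept)"))
  } else if (spec$random == "intercept_slope") {
    tv <- md[[spec$time]]
    if (!is.numeric(tv))
      stop("random slope requires a numeric time variable")
    Z <- cbind("(Intercept)" = 1, time = tv)
  }

  occasion <- NULL
  if (spec$structure %in% c("cs", "un") && !is.null(spec$time))
    occasion <- factor(md[[spec$time]])
  if (spec$structure == "un") {
    occ_levels <- levels(occasion)
    tab <- table(subject, occasion)
    bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
    if (length(bad))
      stop("unstructured covariance requires exactly one observation per ",
           "occasion per subject; offending subject(s): ",
           paste(bad, collapse = ", "))
    if (nlevels(subject) <= nlevels(occasion))
      stop("unstructured covariance needs more subjects than occasions")
  }

  w <- if (!is.null(spec$weights)) {
    wv <- md[[spec$weights]]
    if (any(!is.finite(wv)) || any(wv <= 0)) stop("weights must be positive")
    as.numeric(wv)
  } else rep(1, nrow(X))

  structure(list(X = X, Z = Z, subject = subject, occasion = occasion,
                 weights = w, n = nrow(X), p = p, rank = qrX$rank,
                 S = nlevels(subject), terms = delete.response(trm),
                 xlev = xlev, metadata = md, spec = spec),
            class = "lmm_design")
}
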