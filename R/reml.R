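# Per-gene REML machinery.
#
# All structures share one computational core: the restricted likelihood
#   -2 l_R(theta) = log|V| + log|X' V^{-1} X| + r' V^{-1} r + (n - p) log(2 pi)
# with V block diagonal by subject. Where the structure admits it, the overall
# scale is profiled out analytically so the numerical search runs over one to
# three parameters only; the asymptotic covariance of the covariance
# parameters is then taken from a finite-difference Hessian of the full
# (unprofiled) criterion on an unconstrained parameterization (log standard
# deviations, atanh / scaled-logit correlations, log-Cholesky for the
# unstructured case).

#' Control parameters for the REML optimizer
#'
#' @param psi_bound Bound on unconstrained covariance parameters (log /
#'   atanh scale); parameters at the bound indicate a boundary (singular)
#'   solution.
#' @param reltol Relative tolerance on the criterion for the simplex search.
#' @param max_restarts Number of dispersed restarts attempted when the
#'   method-of-moments start fails to converge.
#' @param fd_step Relative central finite-difference step used for the
#'   Satterthwaite gradient and the criterion Hessian.
#' @return A list of class `"reml_control"`.
#' @export
reml_control <- function(psi_bound = 20, reltol = 1e-12, max_restarts = 3,
                         fd_step = 1e-4) {
  structure(list(psi_bound = psi_bound, reltol = reltol,
                 max_restarts = max_restarts, fd_step = fd_step),
            class = "reml_control")
}

# ---- problem container ------------------------------------------------------

.make_prob <- function(y, design) {
  spec <- design$spec
  ord <- if (!is.null(design$occasion))
    order(design$subject, design$occasion) else order(design$subject)
  subject <- design$subject[ord]
  m <- as.vector(table(subject))
  bend <- cumsum(m)
  bstart <- c(1L, head(bend, -1L) + 1L)
  Xs <- design$X[ord, , drop = FALSE]
  Zs <- if (!is.null(design$Z)) design$Z[ord, , drop = FALSE] else NULL
  ws <- design$weights[ord]
  occ <- if (!is.null(design$occasion)) as.integer(design$occasion[ord]) else NULL
  balanced <- length(unique(m)) == 1L
  if (balanced) {
    mm <- m[1]
    blk <- function(v) matrix(v, nrow = mm)
    if (!is.null(Zs)) {
      zb <- blk(Zs[, 1])
      for (j in seq_len(ncol(Zs))) {
        zj <- blk(Zs[, j])
        if (max(abs(zj - zj[, 1])) > 1e-12) { balanced <- FALSE; break }
      }
    }
    if (balanced && max(abs(blk(ws) - blk(ws)[, 1])) > 1e-12) balanced <- FALSE
    if (balanced && !is.null(occ) &&
        max(abs(blk(occ) - blk(occ)[, 1])) > 0) balanced <- FALSE
  }
  list(y = y[ord], X = Xs, Z = Zs, w = ws, occ = occ, ord = ord,
       subject = subject, m = m, mmax = max(m), bstart = bstart, bend = bend,
       n = design$n, p = design$p, S = design$S, balanced = balanced,
       spec = spec)
}

# ---- criterion pieces -------------------------------------------------------

# Vt: shared per-subject covariance template (balanced designs);
# Vlist: per-subject covariance blocks. Returns NULL if V or X'V^{-1}X is not
# numerically positive definite.
.reml_pieces <- function(prob, Vt = NULL, Vlist = NULL) {
  n <- prob$n; p <- prob$p
  if (!is.null(Vt)) {
    ch <- tryCatch(chol(Vt), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    W <- chol2inv(ch)
    mm <- nrow(Vt)
    logdetV <- 2 * prob$S * sum(log(diag(ch)))
    Xt <- matrix(W %*% matrix(prob$X, nrow = mm), nrow = n)
    yt <- as.vector(W %*% matrix(prob$y, nrow = mm))
    M <- crossprod(prob$X, Xt)
    Xty <- as.vector(crossprod(Xt, prob$y))
    yty <- sum(prob$y * yt)
  } else {
    logdetV <- 0
    M <- matrix(0, p, p)
    Xty <- numeric(p)
    yty <- 0
    for (i in seq_len(prob$S)) {
      idx <- prob$bstart[i]:prob$bend[i]
      ch <- tryCatch(chol(Vlist[[i]]), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      logdetV <- logdetV + 2 * sum(log(diag(ch)))
      A <- backsolve(ch, prob$X[idx, , drop = FALSE], transpose = TRUE)
      b <- backsolve(ch, prob$y[idx], transpose = TRUE)
      M <- M + crossprod(A)
      Xty <- Xty + as.vector(crossprod(A, b))
      yty <- yty + sum(b * b)
    }
  }
  Rm <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(Rm)) return(NULL)
  beta <- backsolve(Rm, backsolve(Rm, Xty, transpose = TRUE))
  quad <- max(yty - sum(Xty * beta), 1e-300)
  list(logdetV = logdetV, logdetM = 2 * sum(log(diag(Rm))),
       quad = quad, beta = as.vector(beta), M = M)
}

.crit_from_pieces <- function(prob, pc) {
  if (is.null(pc)) return(1e10)
  pc$logdetV + pc$logdetM + pc$quad + (prob$n - prob$p) * log(2 * pi)
}

.crit_prof_from_pieces <- function(prob, pc) {
  if (is.null(pc)) return(1e10)
  np <- prob$n - prob$p
  s2 <- pc$quad / np
  np * (log(2 * pi) + log(s2) + 1) + pc$logdetV + pc$logdetM
}

# ---- structure definitions --------------------------------------------------

# Each structure provides:
#   k           length of the full unconstrained parameter x
#   prof        whether a profiled (scale-free) criterion is used
#   kp          length of the profiled parameter psi (if prof)
#   V0_blocks(psi)  covariance template(s) up to the profiled scale
#   V_blocks(x)     full covariance blocks
#   x_of(psi, s2)   assemble full x from psi and the profiled scale
#   theta_of(x)     named natural-scale covariance parameters
#   start()         method-of-moments start + dispersed alternatives
#   singular(theta) boundary flag
.ols_resid <- function(prob) {
  qr.resid(qr(prob$X), prob$y)
}

.mom_ri <- function(prob) {
  r <- .ols_resid(prob)
  msw_num <- 0
  means <- numeric(prob$S)
  for (i in seq_len(prob$S)) {
    idx <- prob$bstart[i]:prob$bend[i]
    means[i] <- mean(r[idx])
    msw_num <- msw_num + sum((r[idx] - means[i])^2)
  }
  msw <- msw_num / max(prob$n - prob$S, 1)
  if (msw <= 0) msw <- max(var(r), 1e-8)
  mbar <- mean(prob$m)
  sb2 <- max(var(means) - msw / mbar, 0.05 * msw)
  c(lambda = sb2 / msw, msw = msw)
}

.structure_def <- function(prob, control) {
  code <- if (prob$spec$random == "intercept") "ri"
    else if (prob$spec$random == "intercept_slope") "ris"
    else if (prob$spec$structure == "cs") { if (prob$mmax == 1L) "cs1" else "cs" }
    else "un"
  bd <- control$psi_bound
  w <- prob$w
  blocks_w <- lapply(seq_len(prob$S),
                     function(i) w[prob$bstart[i]:prob$bend[i]])

  if (code == "ri") {
    V0 <- function(lambda) {
      if (prob$balanced) {
        wi <- blocks_w[[1]]
        list(Vt = diag(1 / wi, length(wi)) + lambda)
      } else {
        list(Vlist = lapply(blocks_w, function(wi)
          diag(1 / wi, length(wi)) + lambda))
      }
    }
    def <- list(
      code = code, k = 2L, prof = TRUE, kp = 1L,
      V0_blocks = function(psi) V0(exp(psi[1])),
      V_blocks = function(x) {
        sb2 <- exp(2 * x[1]); se2 <- exp(2 * x[2])
        if (prob$balanced) {
          wi <- blocks_w[[1]]
          list(Vt = se2 * diag(1 / wi, length(wi)) + sb2)
        } else {
          list(Vlist = lapply(blocks_w, function(wi)
            se2 * diag(1 / wi, length(wi)) + sb2))
        }
      },
      x_of = function(psi, s2) c(0.5 * log(s2 * exp(psi[1])), 0.5 * log(s2)),
      theta_of = function(x) c(sigma_b2 = exp(2 * x[1]), sigma_e2 = exp(2 * x[2])),
      start = function() {
        mom <- .mom_ri(prob)
        l0 <- min(max(mom["lambda"], 1e-6), 1e6)
        list(log(l0), log(l0) + 3, log(l0) - 3, 0)
      },
      singular = function(th) {
        tot <- th[["sigma_b2"]] + th[["sigma_e2"]]
        th[["sigma_b2"]] <= prob$spec$singular_tol * tot
      },
      re_names = c("sigma_b2", "sigma_e2"))
    return(def)
  }

  if (code == "ris") {
    Zb <- lapply(seq_len(prob$S), function(i)
      prob$Z[prob$bstart[i]:prob$bend[i], , drop = FALSE])
    mk_blocks <- function(Gt, resid_scale) {
      if (prob$balanced) {
        wi <- blocks_w[[1]]; Zi <- Zb[[1]]
        list(Vt = resid_scale * diag(1 / wi, length(wi)) + Zi %*% Gt %*% t(Zi))
      } else {
        list(Vlist = lapply(seq_len(prob$S), function(i) {
          wi <- blocks_w[[i]]
          resid_scale * diag(1 / wi, length(wi)) +
            Zb[[i]] %*% Gt %*% t(Zb[[i]])
        }))
      }
    }
    Gt_of <- function(lb, ls, rho) {
      cv <- rho * sqrt(lb * ls)
      matrix(c(lb, cv, cv, ls), 2, 2)
    }
    def <- list(
      code = code, k = 4L, prof = TRUE, kp = 3L,
      V0_blocks = function(psi)
        mk_blocks(Gt_of(exp(psi[1]), exp(psi[2]), tanh(psi[3])), 1),
      V_blocks = function(x) {
        se2 <- exp(2 * x[4])
        mk_blocks(Gt_of(exp(2 * x[1]), exp(2 * x[2]), tanh(x[3])), se2)
      },
      x_of = function(psi, s2)
        c(0.5 * log(s2 * exp(psi[1])), 0.5 * log(s2 * exp(psi[2])),
          psi[3], 0.5 * log(s2)),
      theta_of = function(x) c(sigma_b2 = exp(2 * x[1]),
                               sigma_s2 = exp(2 * x[2]),
                               rho_bs = tanh(x[3]),
                               sigma_e2 = exp(2 * x[4])),
      start = function() {
        mom <- .mom_ri(prob)
        l0 <- min(max(mom[["lambda"]], 1e-6), 1e6)
        tv <- prob$Z[, 2]
        sc <- max(var(tv), 1e-2)
        list(c(log(l0), log(0.25 * l0 / sc), 0),
             c(log(l0) + 3, log(0.25 * l0 / sc) + 3, 0),
             c(log(l0) - 3, log(0.25 * l0 / sc) - 3, 0),
             c(0, 0, 0))
      },
      singular = function(th) {
        tot <- th[["sigma_b2"]] + th[["sigma_s2"]] + th[["sigma_e2"]]
        th[["sigma_b2"]] <= prob$spec$singular_tol * tot ||
          th[["sigma_s2"]] <= prob$spec$singular_tol * tot ||
          abs(th[["rho_bs"]]) >= 1 - 1e-3
      },
      re_names = c("sigma_b2", "sigma_s2", "rho_bs", "sigma_e2"))
    return(def)
  }

  if (code == "cs") {
    lo <- -1 / (prob$mmax - 1)
    rho_of <- function(u) lo + (1 - lo) * plogis(u)
    mkR <- function(wi, rho) {
      mi <- length(wi)
      R <- matrix(rho, mi, mi); diag(R) <- 1
      d <- 1 / sqrt(wi)
      R * tcrossprod(d)
    }
    def <- list(
      code = code, k = 2L, prof = TRUE, kp = 1L,
      V0_blocks = function(psi) {
        rho <- rho_of(psi[1])
        if (prob$balanced) list(Vt = mkR(blocks_w[[1]], rho))
        else list(Vlist = lapply(blocks_w, mkR, rho = rho))
      },
      V_blocks = function(x) {
        s2 <- exp(2 * x[1]); rho <- rho_of(x[2])
        if (prob$balanced) list(Vt = s2 * mkR(blocks_w[[1]], rho))
        else list(Vlist = lapply(blocks_w, function(wi) s2 * mkR(wi, rho)))
      },
      x_of = function(psi, s2) c(0.5 * log(s2), psi[1]),
      theta_of = function(x) c(sigma2 = exp(2 * x[1]), rho = rho_of(x[2])),
      start = function() {
        mom <- .mom_ri(prob)
        icc <- mom[["lambda"]] / (1 + mom[["lambda"]])
        icc <- min(max(icc, lo + 0.02 * (1 - lo)), 0.98)
        u0 <- qlogis((icc - lo) / (1 - lo))
        list(u0, u0 + 3, u0 - 3, 0)
      },
      singular = function(th) {
        th[["rho"]] >= 1 - 1e-4 * (1 - lo) ||
          th[["rho"]] <= lo + 1e-4 * (1 - lo)
      },
      re_names = c("sigma2", "rho"))
    return(def)
  }

  if (code == "cs1") {
    def <- list(
      code = code, k = 1L, prof = TRUE, kp = 0L,
      V0_blocks = function(psi) {
        if (prob$balanced) list(Vt = diag(1 / blocks_w[[1]], 1))
        else list(Vlist = lapply(blocks_w, function(wi) diag(1 / wi, 1)))
      },
      V_blocks = function(x) {
        s2 <- exp(2 * x[1])
        if (prob$balanced) list(Vt = s2 * diag(1 / blocks_w[[1]], 1))
        else list(Vlist = lapply(blocks_w, function(wi) s2 * diag(1 / wi, 1)))
      },
      x_of = function(psi, s2) 0.5 * log(s2),
      theta_of = function(x) c(sigma2 = exp(2 * x[1]), rho = 0),
      start = function() list(numeric(0)),
      singular = function(th) FALSE,
      re_names = c("sigma2", "rho"))
    return(def)
  }

  # unstructured: log-Cholesky over the m x m occasion covariance
  mocc <- length(unique(prob$occ))
  ltri <- which(lower.tri(matrix(0, mocc, mocc), diag = TRUE), arr.ind = TRUE)
  is_diag <- ltri[, 1] == ltri[, 2]
  kU <- nrow(ltri)
  L_of <- function(x) {
    L <- matrix(0, mocc, mocc)
    v <- x
    v[is_diag] <- exp(v[is_diag])
    L[ltri] <- v
    L
  }
  x_of_Sigma <- function(Sig) {
    L <- t(chol(Sig))
    v <- L[ltri]
    v[is_diag] <- log(v[is_diag])
    v
  }
  occ_blocks <- lapply(seq_len(prob$S), function(i)
    prob$occ[prob$bstart[i]:prob$bend[i]])
  def <- list(
    code = "un", k = kU, prof = FALSE, kp = kU,
    V_blocks = function(x) {
      L <- L_of(x)
      Sig <- tcrossprod(L)
      if (prob$balanced) {
        wi <- blocks_w[[1]]; oi <- occ_blocks[[1]]
        d <- 1 / sqrt(wi)
        list(Vt = Sig[oi, oi] * tcrossprod(d))
      } else {
        list(Vlist = lapply(seq_len(prob$S), function(i) {
          d <- 1 / sqrt(blocks_w[[i]])
          Sig[occ_blocks[[i]], occ_blocks[[i]]] * tcrossprod(d)
        }))
      }
    },
    theta_of = function(x) {
      Sig <- tcrossprod(L_of(x))
      v <- Sig[ltri]
      names(v) <- paste0("sigma_", ltri[, 1], "_", ltri[, 2])
      v
    },
    x_of_Sigma = x_of_Sigma,
    start = function() {
      r <- .ols_resid(prob)
      Rm <- matrix(NA_real_, mocc, prob$S)
      for (i in seq_len(prob$S))
        Rm[occ_blocks[[i]], i] <- r[prob$bstart[i]:prob$bend[i]]
      Sig0 <- tryCatch(cov(t(Rm)), error = function(e) NULL)
      if (is.null(Sig0) || anyNA(Sig0) ||
          inherits(tryCatch(chol(Sig0), error = function(e) e, "error"),
                   "error") || any(diag(Sig0) <= 0))
        Sig0 <- diag(max(var(r), 1e-6), mocc)
      x0 <- x_of_Sigma(Sig0)
      list(x0, x0 + 0.5, x0 - 0.5, x_of_Sigma(diag(max(var(r), 1e-6), mocc)))
    },
    singular = function(th) {
      Sig <- matrix(0, mocc, mocc)
      Sig[ltri] <- th
      Sig <- Sig + t(Sig) - diag(diag(Sig))
      ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
      min(ev) <= prob$spec$singular_tol * max(ev)
    },
    re_names = paste0("sigma_", ltri[, 1], "_", ltri[, 2]))
  def
}

# ---- pseudo-inverse of the criterion Hessian --------------------------------

.pinv_sym <- function(H, tol = 1e-8) {
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1e-12)
  if (!any(keep)) return(matrix(0, nrow(H), ncol(H)))
  U <- e$vectors[, keep, drop = FALSE]
  U %*% (t(U) / e$values[keep])
}

# ---- main fitting routine ---------------------------------------------------

#' Fit one gene's linear mixed model by REML
#'
#' Maximizes the restricted likelihood over the covariance parameters on an
#' unconstrained scale (overall scale profiled out where possible),
#' computes generalized-least-squares fixed effects at the optimum, and
#' precomputes the ingredients of Satterthwaite degree-of-freedom tests: the
#' asymptotic covariance of the covariance-parameter estimates (from a
#' central finite-difference Hessian of the criterion) and the derivatives
#' of the fixed-effect covariance with respect to each covariance parameter.
#'
#' @param y Numeric response vector (one gene's transformed expression).
#' @param design Output of [build_design()].
#' @param weights Optional per-observation weights overriding the design's
#'   (e.g. a row of a precision-weight matrix).
#' @param control A [reml_control()].
#' @return An object of class `"seqlmm_fit"`; see the package vignette for
#'   the field layout.
#' @export
reml_fit <- function(y, design, weights = NULL, control = reml_control()) {
  stopifnot(inherits(design, "lmm_design"))
  y <- as.numeric(y)
  if (length(y) != design$n) stop("length(y) must match the design rows")
  if (anyNA(y)) stop("missing values in y are not supported")
  if (sd(y) < 1e-12)
    return(.failed_fit(design, reason = "constant response (non-estimable)"))
  if (!is.null(weights)) {
    design$weights <- as.numeric(weights)
    if (any(design$weights <= 0)) stop("weights must be positive")
  }
  prob <- .make_prob(y, design)
  def <- .structure_def(prob, control)
  if (def$code == "cs1")
    warning("only one observation per subject: the compound-symmetry ",
            "correlation is not identified; fitting OLS with rho pinned at 0")
  bd <- control$psi_bound

  f_prof <- function(psi) {
    if (any(abs(psi) > bd + 5)) return(1e10)
    blocks <- def$V0_blocks(psi)
    .crit_prof_from_pieces(prob, .reml_pieces(prob, blocks$Vt, blocks$Vlist))
  }
  f_full <- function(x) {
    if (any(abs(x) > bd + 15)) return(1e10)
    blocks <- def$V_blocks(x)
    .crit_from_pieces(prob, .reml_pieces(prob, blocks$Vt, blocks$Vlist))
  }

  converged <- TRUE
  if (def$prof && def$kp == 0L) {
    # pure OLS (e.g. compound symmetry with one observation per subject)
    pc0 <- local({ b <- def$V0_blocks(numeric(0));
      .reml_pieces(prob, b$Vt, b$Vlist) })
    s2 <- pc0$quad / (prob$n - prob$p)
    x_hat <- def$x_of(numeric(0), s2)
  } else if (def$prof && def$kp == 1L) {
    opt <- optimize(function(u) f_prof(u), c(-bd, bd), tol = 1e-7)
    cand <- c(opt$minimum, -bd, bd)
    vals <- c(opt$objective, f_prof(-bd), f_prof(bd))
    psi_hat <- cand[which.min(vals)]
    if (min(vals) >= 1e10) converged <- FALSE
    pc0 <- local({ b <- def$V0_blocks(psi_hat)
      .reml_pieces(prob, b$Vt, b$Vlist) })
    s2 <- pc0$quad / (prob$n - prob$p)
    x_hat <- def$x_of(psi_hat, s2)
  } else {
    obj <- if (def$prof) f_prof else f_full
    starts <- def$start()
    best <- NULL
    for (si in seq_along(starts)) {
      st <- starts[[si]]
      res <- tryCatch(
        optim(st, obj, method = "Nelder-Mead",
              control = list(reltol = control$reltol, maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(res)) {
        # simplex restart from the solution to escape premature collapse
        res2 <- tryCatch(
          optim(res$par, obj, method = "Nelder-Mead",
                control = list(reltol = control$reltol, maxit = 1000)),
          error = function(e) NULL)
        if (!is.null(res2) && res2$value < res$value) res <- res2
      }
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
      ok <- !is.null(best) && best$value < 1e9 && best$convergence == 0
      if (ok && si >= 1 + 0) break  # MoM start succeeded; skip extra restarts
      if (si >= 1 + control$max_restarts) break
    }
    if (is.null(best) || best$value >= 1e9) {
      converged <- FALSE
      best <- list(par = starts[[1]], value = 1e10)
    } else if (best$convergence != 0) converged <- FALSE
    if (def$prof) {
      pc0 <- local({ b <- def$V0_blocks(best$par)
        .reml_pieces(prob, b$Vt, b$Vlist) })
      if (is.null(pc0)) return(.failed_fit(design, "covariance not positive definite"))
      s2 <- pc0$quad / (prob$n - prob$p)
      x_hat <- def$x_of(best$par, s2)
    } else {
      x_hat <- best$par
    }
  }

  blocks <- def$V_blocks(x_hat)
  pc <- .reml_pieces(prob, blocks$Vt, blocks$Vlist)
  if (is.null(pc))
    return(.failed_fit(design, "covariance not positive definite at optimum"))
  crit <- .crit_from_pieces(prob, pc)
  beta <- setNames(pc$beta, colnames(design$X))
  vcov_beta <- chol2inv(chol(pc$M))
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  theta <- def$theta_of(x_hat)

  # finite-difference Hessian of the full criterion -> vcov of x_hat
  k <- def$k
  h <- control$fd_step * (abs(x_hat) + 1)
  f0 <- crit
  H <- matrix(0, k, k)
  fp <- fm <- numeric(k)
  for (j in seq_len(k)) {
    ej <- numeric(k); ej[j] <- h[j]
    fp[j] <- f_full(x_hat + ej)
    fm[j] <- f_full(x_hat - ej)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  if (k > 1) {
    for (j in seq_len(k - 1)) for (l in (j + 1):k) {
      ej <- numeric(k); ej[j] <- h[j]
      el <- numeric(k); el[l] <- h[l]
      H[j, l] <- H[l, j] <-
        (f_full(x_hat + ej + el) - f_full(x_hat + ej - el) -
         f_full(x_hat - ej + el) + f_full(x_hat - ej - el)) /
        (4 * h[j] * h[l])
    }
  }
  A <- 2 * .pinv_sym(H)

  # derivatives of vcov(beta) with respect to each unconstrained parameter
  vb_of <- function(x) {
    b <- def$V_blocks(x)
    pcx <- .reml_pieces(prob, b$Vt, b$Vlist)
    if (is.null(pcx)) return(NULL)
    chol2inv(chol(pcx$M))
  }
  dVb <- array(0, dim = c(prob$p, prob$p, k))
  for (j in seq_len(k)) {
    ej <- numeric(k); ej[j] <- h[j]
    vp <- vb_of(x_hat + ej); vm <- vb_of(x_hat - ej)
    if (is.null(vp)) vp <- vcov_beta
    if (is.null(vm)) vm <- vcov_beta
    dVb[, , j] <- (vp - vm) / (2 * h[j])
  }

  # natural-scale covariance of theta via a numerical delta method
  J <- matrix(0, length(theta), k)
  for (j in seq_len(k)) {
    ej <- numeric(k); ej[j] <- h[j]
    J[, j] <- (def$theta_of(x_hat + ej) - def$theta_of(x_hat - ej)) / (2 * h[j])
  }
  theta_vcov <- J %*% A %*% t(J)
  dimnames(theta_vcov) <- list(names(theta), names(theta))

  singular <- def$singular(theta)
  res_marg <- prob$y - as.vector(prob$X %*% beta)
  scaled <- .scaled_residuals(prob, def, x_hat, theta, blocks, res_marg)
  unord <- order(prob$ord)

  structure(list(
    beta = beta, vcov_beta = vcov_beta, theta = theta,
    theta_vcov = theta_vcov, reml_criterion = crit, converged = converged,
    singular = singular, estimable = TRUE, n_obs = prob$n,
    n_subjects = prob$S, rank_X = design$rank,
    df_residual = prob$n - design$rank, structure = def$code,
    x = x_hat, A = A, dVb = dVb,
    fitted = as.vector(design$X %*% beta),
    resid_marginal = res_marg[unord],
    resid_conditional = scaled$cond[unord],
    resid_scaled = scaled$scaled[unord],
    message = ""), class = "seqlmm_fit")
}

.scaled_residuals <- function(prob, def, x_hat, theta, blocks, res_marg) {
  cond <- res_marg
  if (def$code %in% c("ri", "ris")) {
    se2 <- theta[["sigma_e2"]]
    if (def$code == "ri") {
      G <- matrix(theta[["sigma_b2"]], 1, 1)
      Zloc <- matrix(1, prob$n, 1)
    } else {
      sb <- sqrt(theta[["sigma_b2"]]); ss <- sqrt(theta[["sigma_s2"]])
      rho <- theta[["rho_bs"]]
      G <- matrix(c(sb^2, rho * sb * ss, rho * sb * ss, ss^2), 2, 2)
      Zloc <- prob$Z
    }
    for (i in seq_len(prob$S)) {
      idx <- prob$bstart[i]:prob$bend[i]
      Vi <- if (!is.null(blocks$Vt)) blocks$Vt else blocks$Vlist[[i]]
      Zi <- Zloc[idx, , drop = FALSE]
      bi <- G %*% crossprod(Zi, solve(Vi, res_marg[idx]))
      cond[idx] <- res_marg[idx] - as.vector(Zi %*% bi)
    }
    scaled <- cond * sqrt(prob$w) / sqrt(se2)
  } else {
    s2 <- if (def$code == "un") {
      # per-observation marginal variance from the occasion diagonal
      th <- theta
      mocc <- (sqrt(8 * length(th) + 1) - 1) / 2
      Sig <- matrix(0, mocc, mocc)
      Sig[lower.tri(Sig, diag = TRUE)] <- th
      Sig <- Sig + t(Sig) - diag(diag(Sig))
      diag(Sig)[prob$occ]
    } else theta[["sigma2"]]
    scaled <- res_marg * sqrt(prob$w) / sqrt(s2)
  }
  list(cond = cond, scaled = scaled)
}

.failed_fit <- function(design, reason) {
  p <- design$p
  structure(list(
    beta = setNames(rep(NA_real_, p), colnames(design$X)),
    vcov_beta = matrix(NA_real_, p, p), theta = NULL, theta_vcov = NULL,
    reml_criterion = NA_real_, converged = FALSE, singular = FALSE,
    estimable = FALSE, n_obs = design$n, n_subjects = design$S,
    rank_X = design$rank, df_residual = design$n - design$rank,
    structure = NA_character_, x = NULL, A = NULL, dVb = NULL,
    fitted = NULL, resid_marginal = NULL, resid_conditional = NULL,
    resid_scaled = NULL, message = reason), class = "seqlmm_fit")
}

#' @export
print.seqlmm_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("Non-estimable fit:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("REML linear mixed model (%s), -2 logLik(REML) = %.4f\n",
              x$structure, x$reml_criterion))
  cat("Fixed effects:\n")
  print(cbind(estimate = x$beta, se = sqrt(diag(x$vcov_beta))))
  cat("Covariance parameters:\n")
  print(x$theta)
  if (x$singular) cat("Note: singular fit (boundary estimate)\n")
  if (!x$converged) cat("Warning: optimizer did not converge\n")
  invisible(x)
}

#' Fit every gene of a transformed matrix
#'
#' Runs [reml_fit()] on each row of the transformed matrix. Per-gene
#' failures are isolated: a gene whose fit errors out is returned as a
#' flagged non-estimable fit and never aborts the run. Results are
#' identical for any worker count (gene chunks are deterministic functions
#' of gene order, and the fits use no random numbers).
#'
#' @param tmat Transformed matrix (genes x samples), e.g. from [vst()];
#'   an optional `attr(tmat, "weights")` matrix supplies per-gene
#'   observation weights.
#' @param metadata Per-sample metadata; if it has a `sample_id` column the
#'   rows are matched to `colnames(tmat)`, otherwise positional order is
#'   used.
#' @param spec A [model_spec()].
#' @param workers Number of forked workers (Unix); 1 = serial.
#' @param control A [reml_control()].
#' @return An object of class `"seqlmm_fits"`: list with `fits` (one
#'   [reml_fit()] result per gene, input order), `genes`, `design`, `spec`.
#' @export
fit_all_genes <- function(tmat, metadata, spec, workers = 1,
                          control = reml_control()) {
  tmat <- as.matrix(tmat)
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% colnames(metadata) && !is.null(colnames(tmat))) {
    if (!setequal(metadata$sample_id, colnames(tmat)))
      stop("sample IDs of the matrix and metadata do not match")
    metadata <- metadata[match(colnames(tmat), metadata$sample_id), ,
                         drop = FALSE]
  } else if (nrow(metadata) != ncol(tmat)) {
    stop("metadata rows must match the matrix columns")
  }
  design <- build_design(metadata, spec)
  wmat <- attr(tmat, "weights")
  fit_one <- function(g) {
    tryCatch(
      reml_fit(tmat[g, ], design,
               weights = if (!is.null(wmat)) wmat[g, ] else NULL,
               control = control),
      error = function(e) .failed_fit(design, conditionMessage(e)))
  }
  idx <- seq_len(nrow(tmat))
  if (workers > 1 && .Platform$OS.type == "unix") {
    chunks <- split(idx, ceiling(idx / ceiling(length(idx) / workers)))
    fits <- do.call(c, parallel::mclapply(
      chunks, function(ch) lapply(ch, fit_one), mc.cores = workers))
    fits <- unname(fits)
  } else {
    fits <- lapply(idx, fit_one)
  }
  genes <- rownames(tmat)
  if (is.null(genes)) genes <- paste0("gene_", idx)
  names(fits) <- genes
  structure(list(fits = fits, genes = genes, design = design, spec = spec),
            class = "seqlmm_fits")
}

#' @export
print.seqlmm_fits <- function(x, ...) {
  ns <- sum(vapply(x$fits, function(f) isTRUE(f$singular), TRUE))
  nc <- sum(vapply(x$fits, function(f) !isTRUE(f$converged), TRUE))
  cat(sprintf("seqlmm fits: %d genes (%d singular, %d non-converged)\n",
              length(x$fits), ns, nc))
  invisible(x)
}
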