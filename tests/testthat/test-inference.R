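# Satterthwaite df, t- and F-tests, BH adjustment, contrast helpers, and
# results-table assembly.

# a fit whose random-intercept variance sits on the zero boundary (OLS limit)
ols_limit_fit <- function(seed = 301) {
  set.seed(seed)
  md <- balanced_metadata(5)
  des <- build_design(md, ri_spec())
  repeat {
    y <- rnorm(nrow(md))
    fit <- reml_fit(y, des)
    if (fit$singular) return(list(fit = fit, y = y, md = md, des = des))
  }
}

test_that("the OLS limit recovers the classical residual df and F-test", {
  ol <- ols_limit_fit()
  fit <- ol$fit
  np <- fit$n_obs - fit$rank_X
  for (cc in list(c(0, 0, 0, 1), c(0, 1, 0, 1), c(1, 0, 0, 0)))
    expect_equal(satterthwaite_df(fit, cc), np, tolerance = 1e-4)

  # F-test against the classical linear-hypothesis computation
  L <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  ft <- f_test_contrasts(fit, L)
  X <- ol$des$X
  bhat <- solve(crossprod(X), crossprod(X, ol$y))
  rss <- sum((ol$y - X %*% bhat)^2)
  s2 <- rss / np
  Fcl <- drop(t(L %*% bhat) %*%
                solve(L %*% solve(crossprod(X)) %*% t(L), L %*% bhat)) /
    (3 * s2)
  expect_equal(ft$statistic, Fcl, tolerance = 1e-8)
  expect_equal(ft$df, np, tolerance = 1e-4)
  expect_equal(ft$p_value, pf(Fcl, 3, np, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("balanced paired within-subject contrast recovers the ANOVA stratum df", {
  set.seed(302)
  md <- balanced_metadata(6)   # 12 subjects, 2 occasions
  des <- build_design(md, ri_spec())
  checked <- 0
  for (i in 1:8) {
    y <- ri_gene(md, sigma_b = 1.2, sigma_e = 0.5)
    fit <- reml_fit(y, des)
    if (fit$singular) next
    checked <- checked + 1
    # within-subject stratum residual df: n - S - (within-stratum terms)
    df_aov <- nrow(md) - 12 - 2
    expect_equal(satterthwaite_df(fit, c(0, 0, 1, 0)), df_aov,
                 tolerance = 0.1)
    expect_equal(satterthwaite_df(fit, c(0, 0, 0, 1)), df_aov,
                 tolerance = 0.1)
  }
  expect_gte(checked, 4)
})

test_that("the finite-difference gradient matches the analytic derivative", {
  set.seed(303)
  md <- balanced_metadata(5)
  des <- build_design(md, ri_spec())
  y <- ri_gene(md, sigma_b = 1, sigma_e = 0.5)
  fit <- reml_fit(y, des)
  sb2 <- fit$theta[["sigma_b2"]]; se2 <- fit$theta[["sigma_e2"]]
  X <- des$X
  si <- as.integer(factor(md$subject))
  Zmat <- outer(si, seq_len(max(si)), "==") * 1
  V <- se2 * diag(nrow(X)) + sb2 * tcrossprod(Zmat)
  Vi <- solve(V)
  Vb <- solve(t(X) %*% Vi %*% X)
  # d vcov(beta) / d sigma_b2 = Vb X'V^-1 ZZ' V^-1 X Vb  (closed form)
  dVb_analytic <- Vb %*% t(X) %*% Vi %*% tcrossprod(Zmat) %*% Vi %*% X %*% Vb
  # stored derivative is w.r.t. log sigma_b; chain rule: /(2 sigma_b2)
  dVb_fd <- fit$dVb[, , 1] / (2 * sb2)
  expect_equal(dVb_fd, unname(dVb_analytic), tolerance = 1e-4)
})

test_that("t-tests behave as Wald tests and respect contrast scaling", {
  set.seed(304)
  md <- balanced_metadata(5)
  des <- build_design(md, ri_spec())
  y <- ri_gene(md, beta = c(2, 0.4, 0.1, 0.6))
  fit <- reml_fit(y, des)
  t3 <- t_test_contrast(fit, c(0, 0, 0, 1))
  expect_equal(t3$estimate, unname(fit$beta[4]))
  expect_equal(t3$se, sqrt(fit$vcov_beta[4, 4]))
  t2x <- t_test_contrast(fit, c(0, 0, 0, 2))
  expect_equal(t2x$estimate, 2 * t3$estimate)
  expect_equal(t2x$se, 2 * t3$se)
  expect_equal(t2x$statistic, t3$statistic)
  expect_equal(t2x$p_value, t3$p_value)
  expect_error(t_test_contrast(fit, c(0, 0, 0, 0)), "zero")
})

test_that("contrast helpers encode the scenario tests", {
  md <- balanced_metadata(5, times = 0:3)
  des <- build_design(md, ri_spec())
  # between groups at the last follow-up: beta1 + 3 beta3
  Lb <- make_contrast(des, "between_at_time", value = 3)
  expect_equal(unname(Lb[1, ]), c(0, 1, 0, 3))
  # within-group change per unit time in the treatment arm: beta2 + beta3
  Lw <- make_contrast(des, "within_change", value = "treatment")
  expect_equal(unname(Lw[1, ]), c(0, 0, 1, 1))
  # interaction (continuous time): a single coefficient
  Li <- make_contrast(des, "interaction")
  expect_equal(unname(Li[1, ]), c(0, 0, 0, 1))

  # categorical time: the interaction test is a joint 3-row contrast
  md$tfac <- factor(md$time)
  des2 <- build_design(md, model_spec(~ group * tfac, random = "intercept"))
  Li2 <- make_contrast(des2, "interaction", time_var = "tfac")
  expect_identical(nrow(Li2), 3L)
  expect_identical(qr(Li2)$rank, 3L)
})

test_that("F reduces to t-squared for single-row contrasts", {
  set.seed(305)
  md <- balanced_metadata(5)
  des <- build_design(md, ri_spec())
  for (i in 1:5) {
    y <- ri_gene(md, beta = c(2, 0.2, 0.1, 0.5))
    fit <- reml_fit(y, des)
    tt <- t_test_contrast(fit, c(0, 1, 0, 2))
    ft <- f_test_contrasts(fit, rbind(c(0, 1, 0, 2)))
    expect_equal(ft$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(ft$p_value, tt$p_value, tolerance = 1e-10)
    expect_equal(ft$df, tt$df, tolerance = 1e-8)
  }
})

test_that("rank-deficient contrast matrices are rejected", {
  set.seed(306)
  md <- balanced_metadata(4)
  des <- build_design(md, ri_spec())
  fit <- reml_fit(ri_gene(md), des)
  L <- rbind(c(0, 1, 0, 0), c(0, 2, 0, 0))
  expect_error(f_test_contrasts(fit, L), "rank deficient")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # NA propagation: missing p excluded from the family size
  p <- c(0.01, NA, 0.04, 0.03, NA, 0.005)
  adj <- bh_adjust(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  expect_equal(adj[!is.na(adj)], c(0.02, 0.04, 0.04, 0.02))

  # permutation invariance and agreement with stats::p.adjust
  set.seed(307)
  q <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(q)[perm], bh_adjust(q[perm]))
  expect_equal(bh_adjust(q), p.adjust(q, "BH"))
})

test_that("summarize_results applies singular exclusion before adjustment", {
  set.seed(308)
  md <- balanced_metadata(4)
  Y <- ri_matrix(30, md, sigma_b = 1.2)
  fits <- fit_all_genes(Y, md, ri_spec())
  # force exactly 3 singular flags for the arithmetic check
  for (g in c(3, 11, 25)) fits$fits[[g]]$singular <- TRUE
  n_sing <- sum(vapply(fits$fits, function(f) f$singular, TRUE))
  cc <- make_contrast(fits, "interaction")

  tab_ex <- summarize_results(fits, cc, exclude_singular = TRUE)
  expect_identical(nrow(tab_ex), 30L - n_sing)
  expect_identical(attr(tab_ex, "n_excluded_singular"), n_sing)
  expect_equal(tab_ex$p_adj, bh_adjust(tab_ex$p_value))

  tab_all <- summarize_results(fits, cc, exclude_singular = FALSE)
  expect_identical(nrow(tab_all), 30L)
  expect_identical(sum(tab_all$singular), n_sing)
  # exclusion changes only membership and p_adj, never the estimates
  shared <- intersect(tab_ex$gene, tab_all$gene)
  expect_equal(tab_ex$estimate[match(shared, tab_ex$gene)],
               tab_all$estimate[match(shared, tab_all$gene)])

  # stable sort by raw p: ties keep input gene order
  srt <- summarize_results(fits, cc, exclude_singular = FALSE,
                           sort_by_p = TRUE)
  expect_identical(srt$gene,
                   tab_all$gene[order(tab_all$p_value,
                                      seq_len(nrow(tab_all)),
                                      na.last = TRUE)])
})
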