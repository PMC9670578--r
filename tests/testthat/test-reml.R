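# REML fitting: closed-form oracles, boundary behaviour, invariances, and
# the equivalence between the random-effects and marginal parameterizations.

test_that("balanced random-intercept REML matches the one-way ANOVA closed form", {
  set.seed(101)
  S <- 8; m <- 3
  md <- data.frame(subject = rep(sprintf("s%02d", 1:S), each = m), time = 0)
  spec <- model_spec(~ 1, random = "intercept")
  des <- build_design(md, spec)
  for (rep_i in 1:5) {
    b <- rnorm(S, 0, 1.2)
    y <- 5 + b[rep(1:S, each = m)] + rnorm(S * m, 0, 0.7)
    fit <- reml_fit(y, des)
    ybar_i <- tapply(y, md$subject, mean)
    msb <- m * var(ybar_i)
    msw <- sum((y - ybar_i[md$subject])^2) / (S * m - S)
    expect_equal(unname(fit$theta["sigma_b2"]), max(0, (msb - msw) / m),
                 tolerance = 1e-6)
    expect_equal(unname(fit$theta["sigma_e2"]), msw, tolerance = 1e-6)
    expect_equal(unname(fit$beta[1]), mean(y), tolerance = 1e-8)
  }
})

test_that("zero between-subject variance drives the fit to the boundary", {
  # With a true zero variance component the REML estimate sits on the
  # boundary whenever the between-subject mean square does not exceed the
  # within-subject one, which happens with probability P(F <= 1) ~ 0.5;
  # the singular flag must track that boundary event.
  set.seed(102)
  md <- balanced_metadata(3)  # 6 subjects x 2 obs
  des <- build_design(md, ri_spec())
  hits <- 0
  for (i in 1:100) {
    y <- rnorm(nrow(md))  # no subject effect at all
    fit <- reml_fit(y, des)
    if (fit$singular) {
      hits <- hits + 1
      expect_lte(fit$theta[["sigma_b2"]],
                 1e-4 * sum(fit$theta[c("sigma_b2", "sigma_e2")]))
    }
  }
  expect_gt(hits, 30)
  expect_lt(hits, 70)
})

test_that("identity weights leave the fit untouched", {
  set.seed(103)
  md <- balanced_metadata(4)
  des <- build_design(md, ri_spec())
  y <- ri_gene(md)
  f1 <- reml_fit(y, des)
  f2 <- reml_fit(y, des, weights = rep(1, nrow(md)))
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$theta, f2$theta)
  expect_equal(f1$reml_criterion, f2$reml_criterion)
})

test_that("random-intercept and compound-symmetry backends are equivalent", {
  set.seed(104)
  md <- balanced_metadata(5, times = 0:2)
  des_ri <- build_design(md, ri_spec())
  des_cs <- build_design(md, model_spec(~ group * time, structure = "cs",
                                        time = "time"))
  n_checked <- 0
  for (i in 1:25) {
    y <- ri_gene(md, sigma_b = 1, sigma_e = 0.6)
    f_ri <- reml_fit(y, des_ri)
    if (f_ri$singular) next
    f_cs <- reml_fit(y, des_cs)
    n_checked <- n_checked + 1
    expect_equal(f_ri$beta, f_cs$beta, tolerance = 1e-6)
    expect_equal(f_ri$reml_criterion, f_cs$reml_criterion, tolerance = 1e-4)
    # variance mapping: sigma^2 = sigma_b^2 + sigma_e^2, rho = ICC
    sb2 <- f_ri$theta[["sigma_b2"]]; se2 <- f_ri$theta[["sigma_e2"]]
    expect_equal(f_cs$theta[["sigma2"]], sb2 + se2, tolerance = 1e-4)
    expect_equal(f_cs$theta[["rho"]], sb2 / (sb2 + se2), tolerance = 1e-4)
  }
  expect_gte(n_checked, 15)
})

test_that("compound symmetry with one observation per subject degrades to OLS", {
  set.seed(105)
  md <- data.frame(subject = sprintf("s%02d", 1:12),
                   group = rep(c("a", "b"), 6), time = 0)
  spec <- model_spec(~ group, structure = "cs", time = "time")
  des <- build_design(md, spec)
  y <- rnorm(12)
  expect_warning(fit <- reml_fit(y, des), "not identified")
  expect_equal(fit$theta[["rho"]], 0)
  ols <- lm(y ~ group, data = md)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$theta[["sigma2"]], summary(ols)$sigma^2, tolerance = 1e-8)
})

test_that("unstructured paired REML equals the sample covariance closed form", {
  set.seed(106)
  S <- 12
  md <- data.frame(subject = rep(sprintf("s%02d", 1:S), each = 2),
                   occ = factor(rep(c("t0", "t1"), S)))
  spec <- model_spec(~ occ, structure = "un", time = "occ")
  des <- build_design(md, spec)
  Y2 <- matrix(rnorm(2 * S), nrow = 2)
  Y2[2, ] <- 0.7 * Y2[1, ] + rnorm(S, 0, 0.6) + 1
  y <- as.vector(Y2)
  fit <- reml_fit(y, des)
  Shat <- cov(t(Y2))  # REML covariance under a saturated occasion mean
  expect_equal(unname(fit$theta),
               c(Shat[1, 1], Shat[2, 1], Shat[2, 2]), tolerance = 1e-6)
  expect_equal(unname(fit$beta),
               unname(c(mean(Y2[1, ]), mean(Y2[2, ]) - mean(Y2[1, ]))),
               tolerance = 1e-8)
})

test_that("the returned criterion is a local optimum", {
  set.seed(107)
  md <- balanced_metadata(4)
  des <- build_design(md, ri_spec())
  y <- ri_gene(md)
  fit <- reml_fit(y, des)
  prob <- seqlmm:::.make_prob(y, des)
  def <- seqlmm:::.structure_def(prob, reml_control())
  f_full <- function(x) {
    b <- def$V_blocks(x)
    seqlmm:::.crit_from_pieces(prob, seqlmm:::.reml_pieces(prob, b$Vt, b$Vlist))
  }
  for (i in 1:50) {
    x_try <- fit$x + rnorm(2, 0, 1)
    expect_gte(f_full(x_try), fit$reml_criterion - 1e-6)
  }
})

test_that("rescaling the response rescales estimates and keeps t-statistics", {
  set.seed(108)
  md <- balanced_metadata(5)
  des <- build_design(md, ri_spec())
  y <- ri_gene(md, beta = c(1, 0.5, 0.2, 0.4))
  f1 <- reml_fit(y, des)
  f3 <- reml_fit(3 * y, des)
  expect_equal(3 * f1$beta, f3$beta, tolerance = 1e-6)
  expect_equal(9 * f1$theta, f3$theta, tolerance = 1e-5)
  cc <- c(0, 0, 0, 1)
  t1 <- t_test_contrast(f1, cc)
  t3 <- t_test_contrast(f3, cc)
  expect_equal(t1$statistic, t3$statistic, tolerance = 1e-6)
  expect_equal(t1$df, t3$df, tolerance = 1e-4)
})

test_that("fit_all_genes preserves order, isolates failures, and is worker-invariant", {
  set.seed(109)
  md <- balanced_metadata(4)
  Y <- ri_matrix(50, md)
  rownames(Y) <- paste0("g", 1:50)
  Y[17, ] <- 5  # constant gene
  fits <- fit_all_genes(Y, md, ri_spec())
  expect_length(fits$fits, 50)
  expect_identical(fits$genes, rownames(Y))
  expect_false(fits$fits[[17]]$estimable)
  expect_true(all(vapply(fits$fits[-17], function(f) f$estimable, TRUE)))

  fits4 <- fit_all_genes(Y, md, ri_spec(), workers = 4)
  b1 <- t(vapply(fits$fits[-17], function(f) f$beta, numeric(4)))
  b4 <- t(vapply(fits4$fits[-17], function(f) f$beta, numeric(4)))
  expect_identical(b1, b4)

  expect_error(fit_all_genes(Y, md[1:5, ], ri_spec()), "match")
})

test_that("metadata with sample_id is matched to matrix columns by name", {
  set.seed(110)
  md <- balanced_metadata(3)
  md$sample_id <- paste0(md$subject, "_t", md$time)
  Y <- ri_matrix(5, md)
  colnames(Y) <- md$sample_id
  f1 <- fit_all_genes(Y, md, ri_spec())
  shuf <- md[sample(nrow(md)), ]
  f2 <- fit_all_genes(Y, shuf, ri_spec())
  expect_equal(f1$fits[[1]]$beta, f2$fits[[1]]$beta)
})
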