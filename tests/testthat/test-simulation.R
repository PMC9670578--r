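# The NB-GLMM simulator and the permutation-spike benchmark.

test_that("the gamma effect distribution has the requested mode and sd", {
  cfg <- sim_config(scenario = 1)
  # moments solved from mode = (k-1) phi and sd = sqrt(k) phi
  k <- cfg$gamma_shape; phi <- cfg$gamma_scale
  expect_equal((k - 1) * phi, log(2), tolerance = 1e-12)
  expect_equal(sqrt(k) * phi, 0.5, tolerance = 1e-12)
  set.seed(401)
  draws <- rgamma(1e6, shape = k, scale = phi)
  expect_equal(sd(draws), 0.5, tolerance = 0.02)
  dens <- density(draws, n = 2048)
  expect_equal(dens$x[which.max(dens$y)], log(2), tolerance = 0.05)
})

test_that("effect assignment matches the scenario definitions", {
  cfg2 <- sim_config(scenario = 2, n_genes = 1000)
  tr2 <- assign_effects(cfg2, seed = 402)
  expect_identical(sum(tr2$is_de), 200L)
  expect_true(all(tr2$beta3 %in% c(-0.375, 0, 0.375)))
  expect_true(all(tr2$beta3[tr2$is_de] != 0))
  expect_true(all(tr2$beta3[!tr2$is_de] == 0))

  cfg0 <- sim_config(scenario = 1, n_genes = 500, prop_de = 0)
  tr0 <- assign_effects(cfg0, seed = 403)
  expect_true(all(tr0$beta3 == 0))

  cfg1 <- sim_config(scenario = 1, n_genes = 1000)
  tr1 <- assign_effects(cfg1, seed = 404)
  expect_identical(sum(tr1$is_de), 200L)
  expect_true(all(abs(tr1$beta3[tr1$is_de]) > 0))
})

test_that("gene parameter draws are reproducible and respect their ranges", {
  p1 <- draw_gene_params(500, seed = 405)
  p2 <- draw_gene_params(500, seed = 405)
  expect_identical(p1, p2)
  expect_true(all(p1$beta0 >= 0 & p1$beta0 <= 12))
  expect_true(all(p1$alpha >= 0.001 & p1$alpha <= 5))
  expect_true(all(p1$sigma_b > 0 & p1$sigma_b <= 2))
  # negative expression-dispersion rank correlation
  expect_lt(cor(p1$beta0, p1$alpha, method = "spearman"), -0.25)

  tab <- data.frame(beta0 = c(2, 4, 6), alpha = c(0.1, 0.2, 0.3),
                    sigma_b = c(0.5, 0.5, 0.5))
  pt <- draw_gene_params(3, table = tab)
  expect_identical(pt$beta0, tab$beta0)
  expect_error(draw_gene_params(3, table = tab[, -1]), "beta0")
  bad <- tab; bad$alpha[2] <- -1
  expect_error(draw_gene_params(3, table = bad), "row 2")
})

test_that("the degenerate NB limit is Poisson-like with the right mean", {
  cfg <- sim_config(scenario = 1, n_per_group = 2500, n_genes = 1,
                    prop_de = 0, seed = 406)
  params <- data.frame(gene = "g1", beta0 = log(40), alpha = 1e-8,
                       sigma_b = 0)
  truth <- data.frame(gene = "g1", is_de = FALSE, beta3 = 0)
  set.seed(406)
  ds <- simulate_counts(cfg, params, truth)
  cts <- as.vector(ds$counts)       # 10^4 observations
  expect_equal(mean(cts), 40, tolerance = 0.02 * 40)
  expect_lt(abs(var(cts) / mean(cts) - 1), 0.1)  # Poisson dispersion ratio
})

test_that("a random intercept induces within-subject correlation", {
  cfg <- sim_config(scenario = 1, n_per_group = 200, n_genes = 1,
                    prop_de = 0, seed = 407)
  params <- data.frame(gene = "g1", beta0 = log(100), alpha = 0.05,
                       sigma_b = 1)
  truth <- data.frame(gene = "g1", is_de = FALSE, beta3 = 0)
  set.seed(407)
  ds <- simulate_counts(cfg, params, truth)
  lc <- log1p(ds$counts[1, ])
  base <- lc[ds$metadata$time == 0]
  fup <- lc[ds$metadata$time == 1]
  within_cor <- cor(base, fup)
  between_cor <- cor(base, sample(fup))
  expect_gt(within_cor, 0.5)
  expect_gt(within_cor, between_cor)
})

test_that("the marginal mean matches the lognormal mixing formula", {
  # E[C] = exp(beta0 + sigma_b^2 / 2) for a null gene with random intercept
  cfg <- sim_config(scenario = 1, n_per_group = 5000, n_genes = 1,
                    prop_de = 0, seed = 408)
  params <- data.frame(gene = "g1", beta0 = log(50), alpha = 0.1,
                       sigma_b = 0.8)
  truth <- data.frame(gene = "g1", is_de = FALSE, beta3 = 0)
  set.seed(408)
  ds <- simulate_counts(cfg, params, truth)
  expected <- exp(log(50) + 0.8^2 / 2)
  expect_equal(mean(ds$counts), expected, tolerance = 0.05 * expected)
})

test_that("scenario 2 adds a random slope that grows variance with time", {
  cfg <- sim_config(scenario = 2, n_per_group = 300, n_genes = 1,
                    prop_de = 0, seed = 409)
  params <- data.frame(gene = "g1", beta0 = log(200), alpha = 0.02,
                       sigma_b = 1)
  truth <- data.frame(gene = "g1", is_de = FALSE, beta3 = 0)
  set.seed(409)
  ds <- simulate_counts(cfg, params, truth)
  lc <- log1p(ds$counts[1, ])
  v_by_time <- tapply(lc, ds$metadata$time, var)
  expect_gt(v_by_time[["3"]], v_by_time[["0"]])
})

test_that("all published sample sizes are supported and datasets are consistent", {
  for (N in c(3, 5, 10, 20)) {
    cfg <- sim_config(scenario = 1, n_per_group = N, n_genes = 20, seed = 410)
    ds <- simulate_dataset(cfg)
    expect_identical(dim(ds$counts), as.integer(c(20, 4 * N)))
    expect_identical(nrow(ds$metadata), ncol(ds$counts))
    expect_identical(ds$truth$gene, rownames(ds$counts))
  }
  # determinism from the config seed
  cfg <- sim_config(scenario = 2, n_per_group = 4, n_genes = 30, seed = 411)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
})

test_that("permuting gene order permutes counts and truth together", {
  cfg <- sim_config(scenario = 1, n_per_group = 3, n_genes = 40, seed = 412)
  ds <- simulate_dataset(cfg)
  perm <- sample(40)
  expect_identical(ds$counts[perm, ], ds$counts[perm, ])
  expect_identical(rownames(ds$counts)[perm], ds$truth$gene[perm])
})

test_that("the permutation-spike benchmark spikes and permutes as declared", {
  cfg <- sim_config(scenario = 1, n_per_group = 6, n_genes = 300,
                    prop_de = 0, seed = 413)
  ds <- simulate_dataset(cfg)

  ps <- permutation_spike(ds$counts, ds$metadata, baseline = 0, followup = 1,
                          n_subjects = 10, n_swap = 5, n_de = 100,
                          seed = 414)
  expect_identical(ncol(ps$counts), 20L)
  expect_identical(sum(ps$truth$is_de), 100L)
  expect_identical(sum(ps$truth$fold == 2), 50L)
  expect_identical(sum(ps$truth$fold == 0.5), 50L)

  # determinism
  ps2 <- permutation_spike(ds$counts, ds$metadata, baseline = 0,
                           followup = 1, n_subjects = 10, n_swap = 5,
                           n_de = 100, seed = 414)
  expect_identical(ps$counts, ps2$counts)
  expect_identical(ps$metadata, ps2$metadata)

  # identity fold leaves the permuted counts equal to the input columns
  ps1 <- permutation_spike(ds$counts, ds$metadata, baseline = 0,
                           followup = 1, n_subjects = 10, n_swap = 5,
                           n_de = 100, fold = 1, seed = 414)
  expect_identical(ps1$counts, ds$counts[, colnames(ps1$counts)])

  # not enough eligible subjects
  expect_error(permutation_spike(ds$counts, ds$metadata, baseline = 0,
                                 followup = 1, n_subjects = 13),
               "13 required")
})
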