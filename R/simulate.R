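# Negative-binomial GLMM simulator for correlated RNA-seq counts, and the
# permutation-spike benchmark.

# Gamma shape/scale solved from mode = (k - 1) * phi and sd = sqrt(k) * phi:
# phi^2 + mode * phi - sd^2 = 0.
.gamma_from_mode_sd <- function(mode, sd) {
  phi <- (-mode + sqrt(mode^2 + 4 * sd^2)) / 2
  k <- 1 + mode / phi
  c(shape = k, scale = phi)
}

#' Configuration of a simulation scenario
#'
#' Scenario 1 is a paired two-group design (baseline and one follow-up,
#' times 0 and 1) with a subject random intercept and gamma-distributed
#' interaction effects (mode `log 2`, sd 0.5, random sign). Scenario 2 has
#' four occasions (times 0-3), a random intercept plus a random slope whose
#' standard deviation is 30% of the intercept's, and fixed interaction
#' effects of +/- 0.375. Group and time main effects are zero in both.
#'
#' @param scenario 1 or 2.
#' @param n_per_group Subjects per group.
#' @param n_genes Number of genes.
#' @param prop_de Proportion of genes with a nonzero interaction effect.
#' @param seed Integer seed recorded with the config and used by
#'   [simulate_dataset()].
#' @param slope_ratio Random-slope SD as a fraction of the random-intercept
#'   SD (scenario 2).
#' @param effect_size Magnitude of the fixed effects in scenario 2.
#' @param times Optional override of the occasion times (strictly
#'   increasing, starting at 0); defaults to `c(0, 1)` for scenario 1 and
#'   `0:3` for scenario 2.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(scenario = 1, n_per_group = 5, n_genes = 2000,
                       prop_de = 0.2, seed = 1, slope_ratio = 0.3,
                       effect_size = 0.375, times = NULL) {
  stopifnot(scenario %in% c(1, 2), prop_de >= 0, prop_de <= 1,
            n_per_group >= 1, n_genes >= 1)
  if (is.null(times)) times <- if (scenario == 1) c(0, 1) else 0:3
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  gp <- .gamma_from_mode_sd(log(2), 0.5)
  structure(list(scenario = scenario, n_per_group = n_per_group,
                 n_genes = n_genes, prop_de = prop_de, times = times,
                 seed = as.integer(seed), slope_ratio = slope_ratio,
                 effect_size = effect_size,
                 gamma_shape = unname(gp["shape"]),
                 gamma_scale = unname(gp["scale"])),
            class = "sim_config")
}

# truncated-distribution quantile helpers (inverse-CDF on a restricted range)
.qnorm_trunc <- function(u, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd); pu <- pnorm(upper, mean, sd)
  qnorm(pl + u * (pu - pl), mean, sd)
}
.qlnorm_trunc <- function(u, meanlog, sdlog, lower, upper) {
  pl <- plnorm(lower, meanlog, sdlog); pu <- plnorm(upper, meanlog, sdlog)
  qlnorm(pl + u * (pu - pl), meanlog, sdlog)
}

#' Draw per-gene simulation parameters
#'
#' The published simulations drew triplets of baseline log-expression,
#' random-intercept variance, and NB dispersion estimated from real
#' repeated-measures datasets; those triplets are not public, so this
#' synthetic stand-in is used: `beta0 ~ Normal(4, 2)` truncated to
#' `[0, 12]` (natural-log scale), `alpha ~ logNormal(log 0.1, 1)` truncated
#' to `[0.001, 5]`, `sigma_b ~ logNormal(log 0.5, 0.5)` truncated to
#' `(0, 2]`, with a Gaussian-copula rank correlation of -0.4 between
#' `beta0` and `alpha` (higher expression, lower dispersion).
#' Alternatively a user-supplied triplet table is passed through verbatim.
#'
#' @param n_genes Number of genes.
#' @param table Optional data.frame with columns `beta0`, `alpha`,
#'   `sigma_b` (and optionally `sigma_s`, `rho_bs`) used verbatim.
#' @param seed Optional seed (uses the current RNG state when `NULL`).
#' @return data.frame with columns `gene`, `beta0`, `alpha`, `sigma_b`.
#' @export
draw_gene_params <- function(n_genes, table = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(table)) {
    table <- as.data.frame(table)
    need <- c("beta0", "alpha", "sigma_b")
    for (col in need) {
      if (!col %in% colnames(table))
        stop("triplet table is missing column '", col, "'")
      bad <- which(!is.finite(table[[col]]))
      if (length(bad))
        stop("malformed triplet table: non-finite '", col, "' in row ",
             bad[1])
    }
    if (any(table$alpha <= 0))
      stop("malformed triplet table: alpha must be positive (row ",
           which(table$alpha <= 0)[1], ")")
    if (nrow(table) != n_genes)
      stop("triplet table has ", nrow(table), " rows but n_genes = ", n_genes)
    if (is.null(table$gene)) table$gene <- paste0("gene_", seq_len(n_genes))
    return(table)
  }
  # Gaussian copula: Pearson correlation of the latent normals chosen so the
  # Spearman correlation of the margins is -0.4
  r <- 2 * sin(-0.4 * pi / 6)
  z1 <- rnorm(n_genes)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_genes)
  beta0 <- .qnorm_trunc(pnorm(z1), 4, 2, 0, 12)
  alpha <- .qlnorm_trunc(pnorm(z2), log(0.1), 1, 0.001, 5)
  sigma_b <- .qlnorm_trunc(runif(n_genes), log(0.5), 0.5, 0, 2)
  data.frame(gene = paste0("gene_", seq_len(n_genes)),
             beta0 = beta0, alpha = alpha, sigma_b = sigma_b,
             stringsAsFactors = FALSE)
}

#' Assign true differential-expression effects
#'
#' Exactly `round(prop_de * n_genes)` genes receive a nonzero
#' group-by-time interaction coefficient `beta3`; group and time main
#' effects are always zero. Scenario 1 draws `|beta3|` from a gamma
#' distribution with mode `log 2` and standard deviation 0.5 (shape and
#' scale solved from those two moments) with random sign; scenario 2 sets
#' `beta3` to `+effect_size` or `-effect_size` with equal probability.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return data.frame of class truth table: `gene` (index), `is_de`,
#'   `beta3`.
#' @export
assign_effects <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_genes
  n_de <- round(config$prop_de * n)
  beta3 <- numeric(n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  if (n_de > 0) {
    mag <- if (config$scenario == 1)
      rgamma(n_de, shape = config$gamma_shape, scale = config$gamma_scale)
    else rep(config$effect_size, n_de)
    sgn <- ifelse(runif(n_de) < 0.5, -1, 1)
    beta3[de_idx] <- sgn * mag
  }
  data.frame(gene = paste0("gene_", seq_len(n)),
             is_de = seq_len(n) %in% de_idx, beta3 = beta3,
             stringsAsFactors = FALSE)
}

#' Simulate correlated RNA-seq counts from the NB GLMM
#'
#' Counts follow `C_gij ~ NB(mu_gij, alpha_g)` with
#' `Var = mu + alpha * mu^2` and
#' `log(mu_gij) = beta0_g + beta3_g * I(treated_i) * t_ij + b_gi0 + b_gi1 t_ij`,
#' random effects `b ~ N(0, Sigma_b)` per subject (intercept only in
#' scenario 1; intercept and slope with `sd(slope) = slope_ratio *
#' sd(intercept)` in scenario 2). No library-size variation is injected by
#' default; `log_offsets` adds optional per-sample log-scale offsets.
#'
#' @param config A [sim_config()].
#' @param params Gene parameters from [draw_gene_params()].
#' @param truth Truth table from [assign_effects()].
#' @param log_offsets Optional per-sample log offsets (default all 0).
#' @param seed Optional seed.
#' @return List with `counts` (gene x sample matrix), `metadata`
#'   (`sample_id`, `subject`, `group`, `time`), `truth`.
#' @export
simulate_counts <- function(config, params, truth, log_offsets = NULL,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_genes <- config$n_genes
  stopifnot(nrow(params) == n_genes, nrow(truth) == n_genes)
  N <- config$n_per_group
  times <- config$times
  m <- length(times)
  S <- 2L * N
  subj <- factor(rep(paste0("subj_", sprintf("%02d", seq_len(S))), each = m))
  grp <- factor(rep(c("control", "treatment"), each = N * m),
                levels = c("control", "treatment"))
  tt <- rep(times, S)
  sample_id <- paste0(as.character(subj), "_t", tt)
  n_samp <- S * m
  if (is.null(log_offsets)) log_offsets <- rep(0, n_samp)
  treat <- as.numeric(grp == "treatment")

  counts <- matrix(0, n_genes, n_samp,
                   dimnames = list(params$gene, sample_id))
  b0 <- matrix(rnorm(n_genes * S), n_genes, S) * params$sigma_b
  eta_fix <- outer(truth$beta3, treat * tt)           # beta1 = beta2 = 0
  eta <- eta_fix + params$beta0 + b0[, rep(seq_len(S), each = m)]
  if (config$scenario == 2) {
    sigma_s <- if (!is.null(params$sigma_s)) params$sigma_s
      else config$slope_ratio * params$sigma_b
    b1 <- matrix(rnorm(n_genes * S), n_genes, S) * sigma_s
    eta <- eta + b1[, rep(seq_len(S), each = m)] *
      matrix(tt, n_genes, n_samp, byrow = TRUE)
  }
  eta <- eta + matrix(log_offsets, n_genes, n_samp, byrow = TRUE)
  mu <- exp(eta)
  if (any(mu > 1e9)) {
    warning("simulated means capped at 1e9")
    mu[mu > 1e9] <- 1e9
  }
  counts[] <- rnbinom(length(mu), mu = mu, size = rep(1 / params$alpha, n_samp))
  metadata <- data.frame(sample_id = sample_id, subject = subj, group = grp,
                         time = tt, stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from the config, then draws gene parameters, assigns
#' effects, and simulates counts.
#'
#' @param config A [sim_config()].
#' @param params Optional pre-drawn gene parameters.
#' @return As [simulate_counts()], plus `params` and `config`.
#' @export
simulate_dataset <- function(config, params = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(params)) params <- draw_gene_params(config$n_genes)
  truth <- assign_effects(config)
  out <- simulate_counts(config, params, truth)
  out$params <- params
  out$config <- config
  out
}

#' Permutation-spike benchmark dataset
#'
#' Builds a semi-synthetic benchmark from a real (or surrogate) count
#' matrix with repeated measures: a fixed number of subjects is sampled
#' without replacement; for half of them the baseline and follow-up labels
#' are exchanged (removing any systematic time effect); then differential
#' expression is created for `n_de` randomly chosen genes by multiplying
#' their follow-up counts by 2 (half of the genes) or 0.5 (the other
#' half), rounding to the nearest integer.
#'
#' @param counts Count matrix.
#' @param metadata Sample metadata with subject and time columns.
#' @param baseline,followup Values of the time column identifying the two
#'   occasions whose labels are permuted/spiked.
#' @param n_subjects Subjects to sample (must all have both occasions).
#' @param n_swap Number of sampled subjects whose occasion labels are
#'   exchanged.
#' @param n_de Number of spiked genes.
#' @param fold Spike fold change (applied as `fold` to half of the spiked
#'   genes and `1/fold` to the rest).
#' @param subject_var,time_var Metadata column names.
#' @param seed Optional seed.
#' @return List with `counts`, `metadata` (rows of the selected subjects,
#'   permuted labels), and `truth` (`gene`, `is_de`, `fold`).
#' @export
permutation_spike <- function(counts, metadata, baseline, followup,
                              n_subjects = 10, n_swap = 5, n_de = 2600,
                              fold = 2, subject_var = "subject",
                              time_var = "time", seed = NULL) {
  counts <- as_count_matrix(counts)
  metadata <- as.data.frame(metadata)
  if (!is.null(seed)) set.seed(seed)
  subj <- as.character(metadata[[subject_var]])
  tv <- metadata[[time_var]]
  has_b <- tapply(tv == baseline, subj, any)
  has_f <- tapply(tv == followup, subj, any)
  eligible <- names(has_b)[has_b & has_f]
  if (length(eligible) < n_subjects)
    stop("only ", length(eligible), " subjects have both occasions; ",
         n_subjects, " required")
  chosen <- sort(sample(eligible, n_subjects))
  keep <- subj %in% chosen
  md <- metadata[keep, , drop = FALSE]
  cm <- counts[, keep, drop = FALSE]
  swap_subj <- sort(sample(chosen, n_swap))
  msub <- as.character(md[[subject_var]])
  for (s in swap_subj) {
    ib <- which(msub == s & md[[time_var]] == baseline)
    if_ <- which(msub == s & md[[time_var]] == followup)
    md[[time_var]][c(ib, if_)] <- c(rep(followup, length(ib)),
                                    rep(baseline, length(if_)))
  }
  n_genes <- nrow(cm)
  if (n_de > n_genes) stop("n_de exceeds the number of genes")
  de_idx <- sort(sample.int(n_genes, n_de))
  up <- rep(FALSE, n_genes)
  if (n_de > 0) {
    half <- de_idx[sample.int(n_de, floor(n_de / 2))]
    up[half] <- TRUE
  }
  foldvec <- rep(1, n_genes)
  foldvec[de_idx] <- ifelse(up[de_idx], fold, 1 / fold)
  fu_cols <- md[[time_var]] == followup
  cm[, fu_cols] <- round(cm[, fu_cols, drop = FALSE] * foldvec)
  truth <- data.frame(gene = rownames(cm), is_de = seq_len(n_genes) %in% de_idx,
                      fold = foldvec, stringsAsFactors = FALSE)
  list(counts = cm, metadata = md, truth = truth)
}
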