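#' One-call differential-expression pipeline
#'
#' Runs the full analysis on a raw count matrix: size factors, dispersion
#' trend, VST, per-gene REML fits, and one results table per requested
#' contrast.
#'
#' @param counts Count matrix (genes x samples).
#' @param metadata Per-sample metadata.
#' @param spec A [model_spec()].
#' @param contrasts Named list of contrast specifications; each element is
#'   either a contrast matrix/vector or a list with `type`/`value`(/
#'   `group_var`/`time_var`) arguments for [make_contrast()].
#' @param exclude_singular Drop singular fits before BH adjustment.
#' @param workers Worker processes for the gene loop.
#' @return List with `results` (named list of tables), `fits`, `vst`
#'   (size factors and trend), `n_singular`.
#' @export
analyze_counts <- function(counts, metadata, spec, contrasts,
                           exclude_singular = TRUE, workers = 1) {
  v <- vst(counts)
  fits <- fit_all_genes(v$transformed, metadata, spec, workers = workers)
  if (is.null(names(contrasts)))
    names(contrasts) <- paste0("contrast_", seq_along(contrasts))
  results <- lapply(contrasts, function(ct) {
    L <- if (is.list(ct) && !is.matrix(ct))
      do.call(make_contrast, c(list(fits), ct)) else ct
    summarize_results(fits, L, exclude_singular = exclude_singular)
  })
  n_singular <- sum(vapply(fits$fits, function(f) isTRUE(f$singular), TRUE))
  list(results = results, fits = fits,
       vst = v[c("size_factors", "trend")], n_singular = n_singular)
}

#' Simulation benchmark of the pipeline
#'
#' Simulates `n_datasets` datasets from a scenario configuration, analyzes
#' each with the requested model, and scores the interaction test against
#' the simulation truth at the given threshold. This is the desk-scale
#' version of the error-rate study: FDR and sensitivity are averaged over
#' datasets and the Monte-Carlo standard error across datasets is
#' reported.
#'
#' @param scenario 1 or 2.
#' @param n_datasets Number of independent datasets.
#' @param n_genes,n_per_group,prop_de Scenario dimensions.
#' @param random Random-effects structure to fit (`"intercept"` or
#'   `"intercept_slope"`).
#' @param threshold BH threshold for discovery.
#' @param seed Base seed; dataset `d` uses `seed + d - 1`.
#' @param workers Worker processes.
#' @return List with `summary` (averaged [confusion_metrics()] row),
#'   `per_dataset` (data.frame of per-dataset FDR/sensitivity), `fdr_se`
#'   (Monte-Carlo SE of the FDR across datasets).
#' @export
simulation_benchmark <- function(scenario = 1, n_datasets = 3,
                                 n_genes = 2000, n_per_group = 5,
                                 prop_de = 0.2, random = "intercept",
                                 threshold = 0.05, seed = 1, workers = 1) {
  spec <- model_spec(~ group * time, random = random,
                     time = if (random == "intercept_slope") "time")
  per <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    cfg <- sim_config(scenario = scenario, n_per_group = n_per_group,
                      n_genes = n_genes, prop_de = prop_de,
                      seed = seed + d - 1)
    ds <- simulate_dataset(cfg)
    an <- analyze_counts(ds$counts, ds$metadata, spec,
                         contrasts = list(interaction = list(
                           type = "interaction")),
                         workers = workers)
    tab <- an$results$interaction
    truth <- ds$truth[match(tab$gene, ds$truth$gene), ]
    per[[d]] <- confusion_metrics(tab$p_adj, truth$is_de,
                                  thresholds = threshold,
                                  p_raw = tab$p_value)
  }
  per_df <- do.call(rbind, per)
  list(summary = average_metrics(per),
       per_dataset = per_df,
       fdr_se = stats::sd(per_df$observed_fdr) / sqrt(n_datasets))
}

#' Permutation-spike benchmark on a surrogate dataset
#'
#' Reproduces the semi-synthetic benchmark procedure at desk scale when the
#' original repeated-measures dataset is not at hand: a null count matrix
#' with three occasions per subject is generated from the NB-GLMM
#' simulator (random intercept, no fixed effects), CPM-filtered (at least
#' `min_cpm` in a third of the samples), and then permuted and spiked with
#' [permutation_spike()] (10 subjects, labels of the first follow-up
#' exchanged for 5 of them, ~20% of genes spiked at folds 2 and 0.5). Each
#' replicate is analyzed with a categorical-time random-intercept model and
#' the follow-up-versus-baseline coefficient is scored against the spike
#' truth.
#'
#' @param n_replicates Number of benchmark replicates.
#' @param n_genes Genes in the surrogate matrix before filtering.
#' @param n_subjects_pool Subjects simulated (>= `n_subjects`).
#' @param n_subjects,n_swap Benchmark procedure parameters.
#' @param spike_fraction Fraction of retained genes spiked.
#' @param threshold BH discovery threshold.
#' @param min_cpm CPM filter threshold.
#' @param seed Base seed.
#' @param workers Worker processes.
#' @return List with `per_replicate` (FDR/power per replicate), `fdr`,
#'   `power` (means), `fdr_se` (Monte-Carlo SE across replicates).
#' @export
spike_benchmark <- function(n_replicates = 3, n_genes = 4000,
                            n_subjects_pool = 12, n_subjects = 10,
                            n_swap = 5, spike_fraction = 0.198,
                            threshold = 0.05, min_cpm = 1, seed = 1,
                            workers = 1) {
  fdr <- pow <- numeric(n_replicates)
  spec <- model_spec(~ tfac, random = "intercept")
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(scenario = 1, n_per_group = ceiling(n_subjects_pool / 2),
                      n_genes = n_genes, prop_de = 0, times = c(0, 1, 2),
                      seed = seed + 2L * r)
    ds <- simulate_dataset(cfg)
    flt <- cpm_filter(ds$counts, min_cpm = min_cpm,
                      min_samples = ceiling(ncol(ds$counts) / 3))
    n_de <- round(spike_fraction * nrow(flt$counts))
    ps <- permutation_spike(flt$counts, ds$metadata, baseline = 0,
                            followup = 1, n_subjects = n_subjects,
                            n_swap = n_swap, n_de = n_de,
                            seed = seed + 2L * r + 1L)
    meta <- ps$metadata
    meta$tfac <- factor(meta$time)
    an <- analyze_counts(ps$counts, meta, spec,
                         contrasts = list(week1 = list(type = "coef",
                                                       value = "tfac1")),
                         workers = workers)
    tab <- an$results$week1
    truth <- ps$truth[match(tab$gene, ps$truth$gene), ]
    ev <- confusion_metrics(tab$p_adj, truth$is_de, thresholds = threshold)
    fdr[r] <- ev$observed_fdr
    pow[r] <- ev$sensitivity
  }
  list(per_replicate = data.frame(replicate = seq_len(n_replicates),
                                  observed_fdr = fdr, power = pow),
       fdr = mean(fdr), power = mean(pow),
       fdr_se = stats::sd(fdr) / sqrt(n_replicates))
}
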