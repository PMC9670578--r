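# Shared generators for small repeated-measures datasets; all fixtures are
# built in code at test time.

balanced_metadata <- function(n_per_group = 5, times = c(0, 1)) {
  S <- 2 * n_per_group
  m <- length(times)
  data.frame(
    subject = rep(sprintf("s%02d", seq_len(S)), each = m),
    group = factor(rep(c("control", "treatment"), each = n_per_group * m),
                   levels = c("control", "treatment")),
    time = rep(times, S),
    stringsAsFactors = FALSE)
}

# one gene's transformed expression under a random-intercept model
ri_gene <- function(md, beta = c(0, 0, 0, 0), sigma_b = 1, sigma_e = 0.5) {
  si <- as.integer(factor(md$subject))
  b <- rnorm(max(si), 0, sigma_b)
  trt <- as.numeric(md$group == "treatment")
  beta[1] + beta[2] * trt + beta[3] * md$time + beta[4] * trt * md$time +
    b[si] + rnorm(nrow(md), 0, sigma_e)
}

# random intercept + slope
ris_gene <- function(md, beta = c(0, 0, 0, 0), sigma_b = 1, sigma_s = 0.3,
                     sigma_e = 0.5) {
  si <- as.integer(factor(md$subject))
  b0 <- rnorm(max(si), 0, sigma_b)
  b1 <- rnorm(max(si), 0, sigma_s)
  trt <- as.numeric(md$group == "treatment")
  beta[1] + beta[2] * trt + beta[3] * md$time + beta[4] * trt * md$time +
    b0[si] + b1[si] * md$time + rnorm(nrow(md), 0, sigma_e)
}

ri_spec <- function() model_spec(~ group * time, random = "intercept")

ri_matrix <- function(n_genes, md, sigma_b = 1, sigma_e = 0.5,
                      beta3 = rep(0, n_genes)) {
  t(vapply(seq_len(n_genes),
           function(g) ri_gene(md, beta = c(2, 0, 0, beta3[g]),
                               sigma_b = sigma_b, sigma_e = sigma_e),
           numeric(nrow(md))))
}
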