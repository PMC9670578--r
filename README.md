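# seqlmm

Differential expression analysis for RNA-seq studies whose designs induce
correlation between observations — longitudinal sampling, paired baseline /
follow-up measurements, repeated measures on the same subjects. The standard
bulk RNA-seq tools assume independent samples; `seqlmm` instead transforms
the counts to an approximately homoskedastic scale and fits one linear mixed
model per gene, with proper repeated-measures inference.

## The model

Counts are first normalized with median-of-ratios size factors and mapped
through a closed-form variance-stabilizing transformation (VST) driven by a
parametric mean–dispersion trend α(μ) = a₀ + a₁/μ:

    u(q) = log2( 2 a₀ q + (1 + a₁) + 2 sqrt( a₀ q (a₀ q + 1 + a₁) ) ) − log2(4 a₀)

which is the antiderivative of 1/sqrt(v(μ)) for the negative-binomial
variance v(μ) = (1 + a₁) μ + a₀ μ², rescaled so u(q) ≈ log₂(q) for large
counts and finite at q = 0.

Each gene g is then modeled as

    Y_gi = X_i β_g + Z_i b_gi + ε_gi ,   b_gi ~ N(0, Σ_b),  ε_gi ~ N(0, Σ_g)

for subject i, fit by REML. Within-subject correlation enters through
exactly one of two mechanisms: subject-level random effects (random
intercept, or intercept + slope), or a marginal residual covariance
(compound symmetric, or unstructured over a fixed occasion set). Contrasts
c'β are tested with Wald t statistics on Satterthwaite denominator degrees
of freedom

    df = 2 (c' V_β c)² / (gᵀ A g),   g_k = ∂(c' V_β(θ) c)/∂θ_k ,

multi-row contrasts with F statistics whose denominator df combines
per-eigendirection Satterthwaite dfs; p-values are Benjamini–Hochberg
adjusted, with singular fits (boundary variance estimates) reported and
optionally excluded from the family.

The package also contains the negative-binomial GLMM simulator (paired
two-group and four-occasion scenarios with random intercepts/slopes) and a
permutation-spike benchmark, so FDR, power, and type-I error claims can be
reproduced at desk scale, plus per-gene residual diagnostics
(Brown–Forsythe and Kolmogorov–Smirnov) and a counts-per-million filter.

## Worked example

```r
library(seqlmm)

# simulate a paired two-group study: 5 subjects/group, baseline + follow-up
cfg <- sim_config(scenario = 1, n_per_group = 5, n_genes = 500,
                  prop_de = 0.2, seed = 101)
ds <- simulate_dataset(cfg)

# normalize + VST, fit one LMM per gene, test the group-by-time interaction
spec <- model_spec(~ group * time, random = "intercept")
an <- analyze_counts(ds$counts, ds$metadata, spec,
                     contrasts = list(interaction = list(type = "interaction")))

an$vst$trend
#> Dispersion trend alpha(mu) = 0.442193 + 0.438947/mu (fit on 497 genes, 4 iterations)
an$n_singular
#> [1] 40

tab <- an$results$interaction
head(tab[order(tab$p_value), ], 3)
#>         gene estimate        se df statistic      p_value        p_adj singular converged
#> 77   gene_82 3.759550 0.2211920  8  16.99677 1.457372e-07 6.703909e-05    FALSE      TRUE
#> 65   gene_68 2.583932 0.1878382  8  13.75616 7.524528e-07 1.730641e-04    FALSE      TRUE
#> 199 gene_215 2.003756 0.1575360  8  12.71935 1.374065e-06 2.106900e-04    FALSE      TRUE

truth <- ds$truth[match(tab$gene, ds$truth$gene), ]
confusion_metrics(tab$p_adj, truth$is_de, thresholds = 0.05, p_raw = tab$p_value)
#>   threshold n_discoveries observed_fdr sensitivity type1_error n_datasets
#> 1      0.05            30   0.03333333   0.3085106  0.06830601          1
```

`estimate` is the interaction effect on the (log₂-like) VST scale, `df` the
Satterthwaite degrees of freedom (here the paired design's within-subject
stratum df of 8), and the observed FDR among the 30 discoveries is below the
nominal 0.05. Forty fits hit a boundary variance estimate and were excluded
from the BH family.

A thin command-line wrapper over the same functions is installed as
`exec/seqlmm` with subcommands `vst`, `fit`, `simulate`, `permute`,
`evaluate`, and `diagnose`.

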