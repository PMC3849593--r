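# ibagng

Integrative Bayesian analysis of multi-platform genomics data with
Normal-Gamma shrinkage.

## The problem

Cancer cohorts are now routinely assayed on several molecular platforms at
once: mRNA expression, DNA methylation, and DNA copy number. These platforms
are not interchangeable predictors — methylation and copy-number changes act
on the phenotype largely *through* their effect on gene expression. `ibagng`
implements a two-stage hierarchical Bayesian model that uses this biological
structure to find prognostic markers for a continuous clinical outcome
(survival time), and to say *which mechanism* — methylation, copy number, or
something else — carries each gene's effect. It is aimed at statisticians and
computational biologists analysing matched multi-platform cohorts (a
TCGA-style glioblastoma cohort is the motivating shape), and at
methodologists who want a tested reference implementation of Normal-Gamma
shrinkage regression with a generalized-inverse-Gaussian Gibbs sampler.

## The model

**Stage 1 — mechanistic model.** For each gene *i*, expression is partitioned
as

    mRNA_i = M_i + CN_i + O_i

where `M_i` is the part attributable to the gene's methylation markers,
`CN_i` the part attributable to its copy-number markers, and `O_i` the
remainder. Each gene's marker block (1–21 methylation and 1–43 copy-number
markers in the motivating cohort) is reduced by PCA, keeping the smallest
number of components that retain ≥ 90% of the variance; `mRNA_i` is regressed
on all retained scores jointly, and the fitted pieces give `M_i` and `CN_i`,
with intercept and residuals folded into `O_i` so the identity holds exactly.
Sparse missing marker values are imputed first (column-mean fill, then a
regression on each marker's three most positively correlated neighbours).

**Stage 2 — clinical model.** With `Y = log(survival days)` (an accelerated
failure time model) and all standardized components stacked into
`X = [M | CN | O]`,

    Y = X beta + eps,   eps ~ N(0, sigma^2 I)
    beta_{j,i} | psi_{j,i} ~ N(0, psi_{j,i})
    psi_{j,i} ~ Gamma(lambda_j, rate 1/(2 gamma_j^2))        # Normal-Gamma prior
    sigma^2 ~ Inv-Gamma(a, b),  lambda_j ~ Exp(c),
    gamma_j^-2 ~ Gamma(a~, rate b~/(2 lambda_j))

with one shrinkage level `j` per platform group (M, CN, O). The Normal-Gamma
scale mixture shrinks small effects harder and large effects less than the
Bayesian lasso's double-exponential prior. All conditionals are conjugate —
the `psi` updates are generalized inverse Gaussian, drawn by a dedicated
rejection sampler (`rgig()`) — except `lambda_j`, which gets a log-scale
random-walk Metropolis-Hastings step auto-tuned during burn-in to a 20–30%
acceptance rate.

**Selection.** A marker matters practically when a unit increase changes
survival by at least a fraction `delta`, i.e. `beta` falls outside
`(log(1 - delta), log(1 + delta))`. From `S` posterior draws the package
reports the exceedance probabilities `p+ = #{beta^(s) > log(1 + delta)}/S`
and `p-`, and flags a marker when either exceeds 0.5.

## Worked example

Generate a GBM-shaped synthetic cohort (163 samples, 49 genes, six planted
prognostic effects of ±0.5 on log survival) and run the full pipeline —
imputation, per-gene decomposition, 4,000 MCMC iterations, selection at
`delta = 0.05`:

```r
library(ibagng)
sim <- generate_omics_data(omics_design(), seed = 11)
fit <- run_full_pipeline(sim$dataset, delta = 0.05,
                         n_iter = 4000, burn_in = 500, seed = 12)
fit
#> <ibag_fit> p = 146 components, 163 samples
#>   flagged markers: 11 (6 positive, 5 negative) at delta = 0.05
#>   genes flagged:   11

dplyr::filter(fit$report, flag != "none") |>
  dplyr::arrange(dplyr::desc(abs(estimate)))
#> # A tibble: 11 x 7
#>    term      gene_id platform estimate  p_plus p_minus flag
#>  1 O:gene34  gene34  O         -0.561  0       1       negative
#>  2 O:gene05  gene05  O         -0.526  0       1       negative
#>  3 CN:gene27 gene27  CN        -0.490  0       1       negative
#>  4 O:gene30  gene30  O          0.451  1       0       positive
#>  5 CN:gene19 gene19  CN         0.384  1       0       positive
#>  6 O:gene16  gene16  O          0.309  0.999   0       positive
#>  7 O:gene06  gene06  O          0.0950 0.700   0.00114 positive
#>  ...
```

The six strongest flags are exactly the six planted effects
(`sim$truth`), each with the correct sign; `estimate` is the posterior mean
on the standardized-component scale, and `p_plus`/`p_minus` are the posterior
probabilities of at least a 5% increase/decrease in survival time per unit of
the component. The remaining weak flags sit barely past the 0.5 rule —
the flag rate on effect-free data stays below 5% (this is checked by the test
suite). `glance(fit$chain)` showed a posterior mean error variance of 0.412
and an MH acceptance rate of 0.31 for this run; `tidy(fit$chain)`,
`autoplot(fit$chain)` and `autoplot(fit$report)` give coefficient tables,
trace plots and the marker-probability figures.

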