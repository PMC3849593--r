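---
title: "Two-stage Bayesian integration of multi-platform genomics: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian integration of multi-platform genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ibagng)
```

## The two-stage model

`ibagng` integrates mRNA expression, DNA methylation and DNA copy number
against a survival outcome by modelling the biology of how these platforms
relate, rather than pooling them as exchangeable predictors.

**Mechanistic stage.** For gene $i$ the expression vector over $n$ samples is
partitioned as
$$\mathrm{mRNA}_i = M_i + CN_i + O_i,$$
where $M_i$ is the methylation-driven part, $CN_i$ the copy-number-driven
part and $O_i$ everything else. A gene typically carries several markers per
platform, so each marker block is first reduced by PCA and the smallest
number of leading components retaining at least 90% of the block variance is
kept ($K$ methylation and $R$ copy-number scores; a single marker passes
through untouched with $K=1$). The gene's expression is then regressed
jointly on $[1, \text{meth scores}, \text{CN scores}]$, and
$M_i = \sum_k X^M_{i,k}\hat B^M_k$, $CN_i = \sum_r X^{CN}_{i,r}\hat B^{CN}_r$,
$O_i = $ intercept $+$ residuals.

Two choices here were genuinely open and are worth recording:

* *Intercept handling.* The decomposition is stated both as "$O_i$ =
  residuals" and as an exact additive identity. A regression without an
  intercept makes the identity hold but leaks the gene's mean expression into
  $M_i$/$CN_i$ through uncentered scores; we include the intercept and fold
  its contribution into $O_i$, so $M_i + CN_i + O_i = \mathrm{mRNA}_i$ holds
  to machine precision (asserted at $10^{-8}$ in the tests) while $M_i$ and
  $CN_i$ remain mean-zero fitted effects. The "other" component is the
  natural home for the baseline level: it is the part of expression not
  explained by the measured platforms.
* *Covariance vs correlation PCA.* Markers within one platform share a
  measurement scale, so blocks are centered but not rescaled before the PCA
  (covariance PCA). `pc_scores(..., scale. = TRUE)` switches to correlation
  PCA when marker variances are not comparable.

**Imputation.** Missing marker cells (sparse in practice: about 5% in
methylation, 0.1% in copy number) are filled in four steps: column-mean fill
into a working matrix; marker–marker Pearson correlations from that matrix;
for each marker with holes, an OLS regression of its observed entries on its
three most positively correlated markers (predictors taken from the working
matrix, so the result is independent of processing order); substitution of
fitted values into the originally missing cells only. Ties in the donor
ranking break by column order; with fewer than three positively correlated
donors the available ones are used, and with none the mean fill stands (both
warn). A column with no observed values is an error.

**Clinical stage.** All components are stacked into a design matrix
$X = [M \,|\, CN \,|\, O]$ — one column per (gene, platform), a gene with no
methylation markers simply contributes no $M$ column — each column
standardized to mean zero, unit sd ($n-1$ denominator), and the outcome is
$Y = \log(\text{survival days})$, i.e. an accelerated failure time model:
$$Y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I_n).$$
The model as written carries no intercept, so $Y$ is centered before
sampling (a `center_y` switch exists); predictions restore the centering
constant.

## The Normal-Gamma hierarchy and its sampler

With platform groups $j \in \{1 (M), 2 (CN), 3 (O)\}$:
$$\beta_{j,i} \mid \psi_{j,i} \sim N(0, \psi_{j,i}), \quad
\psi_{j,i} \sim \mathrm{Gamma}\!\left(\lambda_j, \text{rate} = \tfrac{1}{2\gamma_j^2}\right),$$
$$\sigma^2 \sim \mathrm{Inv\text{-}Gamma}(a, b), \quad
\lambda_j \sim \mathrm{Exp}(c), \quad
\gamma_j^{-2} \sim \mathrm{Gamma}\!\left(\tilde a, \text{rate} = \tfrac{\tilde b}{2\lambda_j}\right).$$

The gamma laws are shape–rate throughout; we verified symbolically that with
this reading every complete conditional below is exactly conjugate, which is
the only parameterization under which that happens:

* $\beta \mid \cdot \sim N\{(X'X + \sigma^2 D_\psi^{-1})^{-1}X'Y,\;
  \sigma^2 (X'X + \sigma^2 D_\psi^{-1})^{-1}\}$ — drawn through one Cholesky
  factorization per iteration (jitter retry on numerical failure);
* $\sigma^2 \mid \cdot \sim \mathrm{Inv\text{-}Gamma}(a + n/2,\; b + \mathrm{RSS}/2)$;
* $\psi_{j,i} \mid \cdot \sim \mathrm{GIG}(p = \lambda_j - \tfrac12,\;
  \chi = \beta_{j,i}^2,\; \psi = \gamma_j^{-2})$;
* $\gamma_j^{-2} \mid \cdot \sim \mathrm{Gamma}\{p_j\lambda_j + \tilde a,\;
  (\tilde b/\lambda_j + \sum_i \psi_{j,i})/2\}$;
* $\lambda_j$: no closed form. Proposal $\lambda_j^* = e^{\sigma_\lambda z}\lambda_j$,
  $z \sim N(0,1)$; the acceptance ratio (prior $\times$ gamma likelihood
  $\times$ Jacobian $\lambda^*/\lambda$) is evaluated entirely in log space.

The scan order is fixed ($\beta$, $\sigma^2$, $\psi$, $\gamma^{-2}$,
$\lambda$ per platform) for reproducibility. Initialization follows the
frequentist route: $\beta^{(0)}$ is the cross-validated lasso estimate
(single penalty), $\sigma^{2(0)}$ its mean squared residual, all scale
parameters start at 1, and $\tilde b$ is the mean squared least-squares
coefficient (ridge-stabilized when $X$ is not full rank). Defaults
$a = b = 0.001$, $c = 1$, $\tilde a = 2$.

**GIG sampling.** The generalized inverse Gaussian conditional is the heart
of the sampler and no installed package provides its RNG, so `rgig()`
implements a rejection sampler in C++: on the log scale around the mode the
GIG log-density is concave and is dominated by a flat centre piece plus two
exponential tails built from tangents; negative shape exponents use the
inversion identity $1/X \sim \mathrm{GIG}(-p, \psi, \chi)$, and $\chi = 0$
with $p>0$ reduces to a gamma draw. A numerically zero $\beta_{j,i}^2$ is
floored at $10^{-12}$ (an exact zero has probability zero but occurs in
floating point, and the GIG is improper at $\chi = 0$, $p \le 0$). The
sampler is validated against Bessel-function moment identities, quadrature
CDFs (Kolmogorov–Smirnov at $\alpha = 0.01$) and the gamma limit.

**MH tuning.** $\sigma_\lambda$ adapts only during burn-in: every 50
iterations the windowed acceptance rate is compared with the 20–30% target
band and the scale is multiplied by 1.25 (too many acceptances) or 0.8 (too
few). After burn-in the scale freezes, so the retained chain is a
time-homogeneous Markov chain. $\lambda_j$ lives in $[10^{-6}, 10^{6}]$;
proposals outside are rejected ($\Gamma(\lambda)$ overflows well inside
double range otherwise).

**Validation strategy.** Beyond per-conditional oracles (closed-form moments,
quadrature) the suite runs a getting-it-right style joint test
(`geweke_check()`): moments of $\beta_1$, $\sigma^2$, $\lambda_1$ from iid
prior draws are compared against a successive-conditional chain that
alternates one Gibbs scan with a fresh data draw, on a $n=10$, $p=3$
instance. That test needs finite fourth moments, so it runs with informative
hyperparameters ($a=6$, $b=5$, $\tilde a = 3$, fixed $\tilde b = 1$) — the
code paths are identical to the analysis defaults.

**Bayesian-lasso comparator.** `blasso_regress()` keeps the identical scan
but replaces the mixing law with $\psi_{j,i} \sim \mathrm{Exp}(\lambda_j)$
(the double-exponential marginal). Its $\psi$ conditional is
$\mathrm{GIG}(\tfrac12, \beta_{j,i}^2, 2\lambda_j)$ — the same `rgig()` —
and $\lambda_j$ is conjugate: with the $\mathrm{Exp}(1)$ prior we adopt
(mirroring $c = 1$ in the Normal-Gamma arm; the comparator's $\lambda$ prior
was an open choice), $\lambda_j \mid \cdot \sim \mathrm{Gamma}(p_j + 1,\,
1 + \sum_i \psi_{j,i})$. One shared rate across platforms is available via
`global_lambda = TRUE`.

## Marker selection

On the log-survival scale a coefficient is practically relevant when a unit
increase in its (standardized) component changes survival by a fraction of at
least $\delta$; the relevance region is $(\log(1-\delta), \log(1+\delta))$,
asymmetric because $|\log(1-\delta)| > \log(1+\delta)$. With $S$ stored
draws, $p_+$ and $p_-$ are the fractions strictly beyond the upper/lower
cutoff, and a marker is flagged when either strictly exceeds $0.5$ — ties at
exactly $0.5$ are not flagged, matching the strict inequalities of the rule.
Because predictors are standardized, "a unit increase" means one sd of the
component; the report also carries the effect per original component unit
(`estimate_raw = estimate / scale`) so both readings are available. The
default $\delta = 0.05$ corresponds to a 5% change in survival time.

## Synthetic data: what it emulates and what it does not

Two generators are first-class, tested code:

* `generate_table1_data()` reproduces the sparse-regression study design:
  $n = 100$ training and $400$ test samples, 90 iid $N(0,1)$ predictors in
  three platform groups of 30, thirty coefficients exactly zero (uniformly
  chosen), the rest iid Laplace$(0, 1/7)$, noise variance 1. These constants
  are the study conditions and are not tuning knobs.
* `generate_omics_data()` emulates the shape of a matched glioblastoma
  cohort: 163 samples, 49 genes, 1–21 methylation and 1–43 copy-number
  markers per gene with exactly one gene lacking methylation data entirely,
  missingness rates of 5% (methylation) and 0.1% (copy number), strictly
  positive survival times. Within each gene a single latent factor with
  loading 0.8 drives the marker block (the within-gene correlation of real
  arrays is not published; one factor plus iid noise is the simplest
  structure that makes the PCA reduction meaningful), the three true
  components are unit-variance latent signals, and expression is their exact
  sum, so the decomposition identity is testable to machine precision. Log
  survival is centred at $\log(365)$ days — a median survival near a year,
  realistic for this disease — with residual sd 0.5, and carries six planted
  effects of $\pm 0.5$ per component sd (a 65% change in survival per sd:
  a strong but plausible prognostic marker, comfortably beyond the
  $\delta = 0.05$ relevance cutoff). Effects alternate in sign and are never
  planted on the methylation slot of the methylation-free gene.

What passing tests on these data do **not** show about real cohorts: real
marker blocks have richer correlation than one factor; platform
measurements carry batch and normalization artefacts the generator omits;
real survival is censored (out of scope here — the model uses uncensored
times only); and gene blocks overlap biologically (shared pathways) whereas
the generator draws genes independently. Recovery rates on synthetic data are
therefore an upper bound on what identical settings would achieve in
practice.

## Numerical choices and degenerate inputs

* Cholesky failures in the $\beta$ update retry with escalating jitter
  ($10^{-8}$ of the mean diagonal, $\times 10$ per retry, 5 tries) before
  aborting; non-finite sampler states abort with the iteration index.
* `pc_scores` treats an all-constant block as "no components" (zero
  methylation contribution) with a warning; the rank guard in
  `decompose_gene` drops lowest-variance scores if $K + R + 1 \ge n$.
* Zero-variance design columns are dropped with a warning before
  standardization; standardization constants are stored for
  back-transformation.
* Equal-tailed credible intervals throughout (quantile type 7).
* Sample alignment across platforms is an id intersection with a logged drop
  list; within the intersection the mRNA matrix's sample order is canonical.
* Least-squares baseline: ML variance estimate RSS$/n$ by default (the
  unbiased $n - p$ variant is a switch), no intercept (the clinical model has
  none and the response is centered); classical $t$ intervals at 95%/90%.
  Cross-validated penalties for the lasso/elastic-net baselines use 10-fold
  CV (fold count is unstated in the motivating analysis; 10 is the glmnet
  default), under the current RNG state so studies are seed-reproducible.

## Problem sizes used by the checks

The replicated simulation study in the tests and in `scripts/acceptance.R`
uses 20 replicates at the full 10,000-iteration/500-burn-in chain length —
averaging over replicates is the honest comparison for a design where a
single dataset's MSE ratios are strongly seed-dependent (n barely exceeds p,
so the least-squares overfit term $\mathrm{tr}\{(X'X)^{-1}\}$ has mean
$p/(n-p-1) = 10$ and substantial spread). Conditional-correctness oracles run
at $10^5$ draws (4 Monte-Carlo-SE bands), the KS checks at $10^4$ draws, the
joint Geweke-style test at $2\times 10^4$ draws per route, and the
planted-effect recovery study at 10 seeds with paired effect-free (null)
runs.

## Known limitations

* No censored-survival likelihood: survival times enter as uncensored
  $\log(t)$. Cohorts with censoring need a different clinical-stage
  likelihood.
* One shrinkage level per platform group; no gene-level grouping or
  spike-and-slab point mass (continuous shrinkage only).
* The mechanistic stage is linear; non-linear platform effects end up in the
  "other" component.
* PCA scores are estimated, not error-free; the clinical stage does not
  propagate stage-1 uncertainty.
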