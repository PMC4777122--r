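---
title: "Finlay-Wilkinson regression: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finlay-Wilkinson regression: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Plant breeders use Finlay-Wilkinson regression to describe how varieties
respond to environment quality in multi-environment trials. The phenotype of
replicate $k$ of variety $i$ in environment $j$ is modeled as the reaction
norm

$$y_{ijk} = \mu + g_i + h_j + b_i h_j + \varepsilon_{ijk},
\qquad \varepsilon_{ijk} \sim N(0, \sigma^2_\varepsilon),$$

where $g_i$ is the variety main effect, $h_j$ the environment effect, and
$b_i$ the variety's deviation from average responsiveness: rewriting the
predictor as $\mu + g_i + (1 + b_i)h_j$ shows that $1 + b_i$ is the expected
change in performance per unit change in environment quality. A variety with
$b_i = 0$ responds exactly averagely (slope 1), $b_i < 0$ means stability,
$b_i > 0$ responsiveness to good environments, and $b_i = -1$ a flat reaction
norm.

`fw()` fits this model two ways.

## The two-step least-squares estimator

The classical procedure first estimates environment quality, then regresses
each line on it:

1. **Step 1** fits the additive model $y = \mu + g_i + h_j + \varepsilon$ by
   least squares under the constraints $\sum_i g_i = 0$ and
   $\sum_j h_j = 0$, using only the non-missing records. Unlike raw
   environment sample means, this adjusts the environment effects for which
   lines happened to be observed in them, which matters in incomplete
   designs. We solve the bordered (Lagrange) normal equations with a dense
   solver: the system is small (varieties + environments + 3), the solution
   is exact, and it is directly checkable against an independent
   sum-contrast fit. On a complete balanced design it reduces to
   $\hat h_j = \bar y_{\cdot j} - \bar y$, exactly.
2. **Step 2** regresses, separately within each line, the line's phenotypes
   on $\hat h_j$ with an intercept but no global mean, so the intercept
   estimates $\mu + g_i$ and the slope estimates $1 + b_i$. The residual
   variance is pooled across lines weighted by each line's residual degrees
   of freedom $n_i - 2$ and reported as `var_e_weighted`.

Both estimation steps treat all effects as fixed; nothing is shrunk. Two
degenerate situations need decisions the classical description leaves open:

* **A line observed at fewer than two distinct environment effects** cannot
  support a slope. We set its $b_i = 0$ and its intercept to the line mean
  minus the mean environment effect at its records, contribute zero degrees
  of freedom to the pooled variance, and flag it in a per-line status
  vector. This keeps the output complete for prediction without letting an
  unidentifiable slope contaminate the variance estimate.
* **An environment with no observed records** cannot be estimated by least
  squares at all and is a hard error; only the Bayesian path can infer such
  an environment (below). Likewise a disconnected variety-environment
  incidence graph makes the constrained system singular, and we report the
  offending component by name rather than returning an arbitrary
  generalized-inverse solution.

Step 2 deliberately regresses on every replicate record rather than on cell
means, so replicated designs weight lines by their true record counts.

## The single-step Bayesian model

The Bayesian formulation keeps the same likelihood but treats $g$, $b$ and
$h$ as random:

$$g \sim N(0, A\sigma^2_g), \quad b \sim N(0, A\sigma^2_b), \quad
h \sim N(0, H\sigma^2_h),$$

with a flat prior on $\mu$ and scaled-inverse-$\chi^2(\nu, S^2)$ priors on
the four variances. $A$ is a covariance between lines — a marker-derived
genomic relationship matrix or a pedigree numerator matrix — and $H$ a
covariance between environment effects. Setting either to the identity
recovers independence. This addresses the known weaknesses of the two-step
procedure: environment effects are estimated jointly with the
genotype-by-environment terms, uncertainty in $\hat h$ propagates into the
slopes, shrinkage reduces sampling variance when many parameters meet
modest data, and relationship information is pooled across relatives.

### Gibbs sampler

The posterior has no closed form; we sample it with a fixed-scan Gibbs
sampler, updating $\mu$, then the blocks $g$, $b$, $h$, then
$\sigma^2_\varepsilon, \sigma^2_g, \sigma^2_b, \sigma^2_h$. Each vector
block has a multivariate normal full conditional with precision
$D/\sigma^2_\varepsilon + K^{-1}/\sigma^2_u$, where $D$ is the diagonal of
per-level sums of squared covariates (counts for $g$, $\sum h_j^2$ for $b$,
$\sum (1+b_i)^2$ for $h$) and $K$ is $A$ or $H$; the location solves the
precision system applied to the per-level residual sums. We draw the whole
block by a Cholesky factorization of the precision each cycle. At the
scales this model is used (hundreds of lines, a handful of environments)
the exact block update is cheap, mixes at least as well as single-site
scans, and each conditional can be verified against its closed form by
clamping the other blocks — the test suite does exactly that. When $A$ (or
$H$) is diagonal the update factorizes into scalar draws and the matrix
work is skipped. Each variance is drawn from its conjugate
scaled-inverse-$\chi^2$ conditional with degrees of freedom $\nu_u + q_u$
and numerator $u^\top K^{-1} u + \nu_u S^2_u$.

Numerical choices:

* $A^{-1}$ and $H^{-1}$ are computed once before sampling. Marker-derived
  relationship matrices are frequently numerically singular (a
  column-centered cross-product always has the ones vector near its null
  space), so a failed factorization triggers a single retry with a jitter
  of $10^{-8} \cdot \mathrm{mean(diag)}$ added to the diagonal, with a
  message. Matrices failing the PSD check at load time (eigenvalues below
  $-10^{-8}$ relative) are rejected outright rather than silently repaired.
* Initialization: $\mu$ at the observed mean, $g = b = 0$, $h$ at centered
  environment means (zero for unobserved environments), variances at their
  prior expectations. Burn-in absorbs the rest; users fitting small or
  noisy data should run longer chains and inspect the stored samples.
* The scan order is fixed, and all randomness flows through R's RNG, so a
  seed makes a chain bit-reproducible. Multiple chains get child seeds
  drawn deterministically from the user seed.
* Records with missing $y$ contribute to no likelihood sum and are **not**
  imputed as latent variables. They still receive fitted values and
  posterior SDs through the predictor identity
  $\hat y = \hat\mu + \hat g_i + \hat h_j + \hat b_i \hat h_j$, which is
  what masked-record cross-validation and prediction of entirely
  unobserved environments rely on. Imputation would add nothing for these
  uses and would make prior-only environments ill-defined.
* No sign or centering constraint is imposed on $h$ or $b$ inside the
  sampler; the zero-mean priors regularize location. Mixing of $\mu$ and
  $h$ is known to be slow in multiplicative models, which is the main
  reason to prefer longer chains over post-hoc recentering.

Posterior means and SDs (including those of $\hat y$, computed per draw,
not by a delta method) are taken over the thinned post-burn-in draws —
the same draws that land in the sample store, so reported summaries and
stored samples can never disagree. Defaults are 5000 cycles, 3000 burn-in,
thinning 5; each chain therefore keeps 400 draws unless configured
otherwise, and draws of the variance components, $\mu$, and the first two
(configurable) entries of $g$, $b$ and $h$ are retained.

### Default hyperparameters

If the user supplies no $(\nu, S^2)$ pairs, all four degrees of freedom
default to 5 and the scales are set so the prior expectations
$E[\sigma^2] = \nu S^2/(\nu - 2)$ partition the sample variance of the
observed phenotypes: one half to residual, one quarter each to intercepts
and slopes, and one half to environments. The environment share is
deliberately generous because the number of environments is typically tiny
and a scaled-inverse-$\chi^2$ with few effective degrees of freedom is
strongly right-skewed; a tight prior there would dominate the data. With
$\nu \le 2$ the prior mean does not exist; such values are accepted with a
warning and the scale falls back to the share itself. These are defaults,
not recommendations — when real prior knowledge about, say, heritability
exists, pass explicit values.

A consequence worth knowing: with few environments the posterior of
$\sigma^2_h$ remains wide, skewed, and noticeably influenced by the prior.
Interval estimates for $\sigma^2_h$ at 4–8 environments should be read as
credibility statements under this prior, not as calibrated frequentist
intervals; the package's own recovery tests show near-nominal coverage for
the residual, intercept and slope variances but materially reduced
coverage for the environment variance at $q = 8$, which is inherent to the
small-$q$ regime rather than to the sampler.

### Borrowing across environments

A nondiagonal $H$ lets environments share information. With an environment
entirely unobserved, its $D$ and residual sums are zero and its
conditional reduces to the conditional prior given the other environment
effects: with two environments correlated at $\rho$, the unobserved
effect's posterior mean is $\rho$ times the observed one's. This is the
mechanism for predicting performance in environments without records, and
it degrades gracefully: with $H = I$ the unobserved effect just centers at
zero.

## The synthetic-data generator

`simulate_fw_table()` draws data from exactly the model above: effects
from their multivariate normal laws (given $A$, $H$ or identities),
residuals iid normal, full-factorial designs with optional replicates, and
a `truth` record sufficient to regenerate the table from its seed. The
default magnitudes (grand mean 4, residual variance 0.3, intercept
variance 0.09, slope variance 0.10, environment variance 0.9) were chosen
once to mirror a typical wheat grain-yield multi-environment trial, where
environment differences dwarf genetic variance; tests and the acceptance
script use these conditions throughout. `simulate_kinship()` builds a
VanRaden-style genomic relationship matrix from iid biallelic dosages with
uniform allele frequencies — the de-facto standard construction — and
`mask_one_env_per_line()` produces the one-record-per-line train/validation
splits used for prediction-accuracy studies.

What the generator does **not** emulate: linkage disequilibrium, population
structure or families (kinship off-diagonals arise only from finite-marker
sampling noise, which is nonetheless real relatedness for the simulated
effects), heterogeneous residual variances across environments, non-normal
traits, and informative missingness. Passing tests on these data therefore
demonstrate correctness of the estimators under the model's own
assumptions, not robustness to the many ways field data violate them.

## Diagnostics

The posterior utilities implement the standard empirical algorithms:
highest-posterior-density intervals as the shortest contiguous window over
the sorted draws covering $\lceil \gamma n \rceil$ points (ties broken at
the lowest index; the conventions match the widely used `coda`
implementation to within discretization), lag-$k$ autocorrelation with the
biased $1/n$ normalization, and Monte Carlo standard errors of chain means
by batch means with $\lfloor\sqrt{n}\rfloor$ batches — simple, testable
against iid and AR(1) closed forms, and adequate for judging whether a
chain was long enough. Multi-chain fits keep per-chain columns everywhere;
pooling across chains is left to the user so that disagreement between
chains (a convergence failure) stays visible. Formal multi-chain
diagnostics are intentionally out of scope; the sample store is plain CSV
so any MCMC toolkit can compute them.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` size their simulations to make
each statistical property measurable while keeping the whole run
comfortable on a single CPU: conditional-distribution checks use $10^5$
clamped draws on toy designs; parameter recovery uses 20 replicates of 300
lines $\times$ 8 environments at 10,000 cycles; the prediction-accuracy
comparison uses one kinship-structured dataset of 200 lines $\times$ 4
environments (250 markers) with 20 masked partitions at 4,000 cycles per
Bayesian fit; the acceptance script uses 250 lines with 400 markers and 10
partitions. These sizes are the package's own choices and are stated here
so results can be reproduced exactly.

## Known limitations

* No latent-variable imputation of missing phenotypes, no non-normal
  likelihoods, no per-environment residual variances.
* No Metropolis or reparameterization remedies for the slow mixing of
  $\mu$ and $h$; the supported remedy is longer chains.
* The two-step estimator cannot handle environments with no observed
  records (by construction); use the Bayesian path with an informative
  $H$.
* Pedigree files are not parsed; supply $A$ as a labeled matrix.
* Interval estimates for the environment variance with very few
  environments are prior-sensitive, as discussed above.
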