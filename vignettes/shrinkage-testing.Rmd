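---
title: "Informative shrinkage testing: model, decisions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informative shrinkage testing: model, decisions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it
implements: the hierarchical model, the test and its decision theory, the
parameters a user can turn, and every numerical convention that affects
results. It states no empirical numbers beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## The model

For gene $g$ and sample $i$, with $Y_{ig}$ the normalized expression on
the $\log_2(\mathrm{CPM}+1)$ scale and $X_i \in \{0,1\}$ the group
indicator,

$$Y_{ig} \sim N(c_g + X_i\beta_g,\ \sigma_g^2),$$

so $\beta_g$ is the gene's log2 fold change and the residual variance is
gene-specific (expression data are strongly heteroscedastic). The prior on
the effect is the heteroscedastic global-local shrinkage prior

$$\beta_g \mid \sigma_g^2, \lambda_g, \tau \sim
  N\!\big(h_g,\ \sigma_g^2\lambda_g^2\tau^2\big),
  \qquad \lambda_g, \tau \sim \mathrm{C}^+(0,1),$$

with $h_g$ a fixed, externally supplied prior effect estimate (an LFC from
another platform or species). Three features matter:

* the prior is centered at $h_g$, not at zero — shrinkage pulls toward the
  external knowledge, not toward "no effect";
* the gene-local scale $\lambda_g$ is learned from the gene's own
  coherence between prior and data: when $|\hat\beta_g - h_g|$ is large,
  $\lambda_g$ inflates and the prior's influence fades (the tests verify
  this monotonicity on bin averages);
* the prior variance carries $\sigma_g^2$, so shrinkage is relative to the
  gene's noise level.

The remaining priors are conjugate: $\sigma_g^2 \sim IG(\xi_1, \xi_2)$ and
$c_g \mid \sigma_g^2 \sim N(0, 10^2\sigma_g^2)$. The hyperparameters
$(\xi_1,\xi_2)$ are set by moment matching
(`fit_variance_hyperparams()`): the inverse-gamma mean and variance are
equated to the empirical mean $m$ and variance $v$ of the per-gene pooled
residual variances, giving $\xi_1 = m^2/v + 2$ (always $> 2$, so the prior
variance is finite) and $\xi_2 = m(\xi_1 - 1)$.

**Assumptions.** Normal residuals on the log scale; a single binary
covariate; prior centers treated as fixed constants (their uncertainty is
absorbed by $\lambda_g$); exchangeability of genes only through the shared
$\tau$ and $(\xi_1,\xi_2)$.

## The test: composite null and Bayesian Credible Ratio

The null is composite, $H_{0g}: \beta_g \in (-\epsilon, \epsilon)$:
only effects larger than a biologically meaningful $\epsilon$ (log2 units;
typically $\log_2 1.2$ or $\log_2 1.5$, a domain choice) count. From the
posterior draws define $\tilde\omega_{0g} = \Pr(|\beta_g| < \epsilon\mid D)$,
$\tilde\omega_{1g} = \Pr(\beta_g \le -\epsilon \mid D)$,
$\tilde\omega_{2g} = \Pr(\beta_g \ge \epsilon \mid D)$, and

$$\mathrm{BCR}_g = \frac{\tilde\omega_{0g}}
  {1 - \min(\tilde\omega_{1g}, \tilde\omega_{2g})} \in [0, 1],$$

rejecting when $\mathrm{BCR}_g < \lambda$. The denominator discounts the
*weaker* tail: evidence is only as strong as the dominant sign direction.
The rule is exactly equivalent to the weighted posterior-odds rule
$(1-\lambda)\tilde\omega_{0g} < \lambda\max(\tilde\omega_{1g},
\tilde\omega_{2g})$, which is the Bayes rule of a three-action decision
problem with 0–$K$ losses and $\lambda = K_0/(K_0 + K_1)$; the test suite
checks the equivalence exactly on $10^5$ random probability triples, and
confirms by exhaustive enumeration on small instances that this rule
minimizes the sign-aware classification risks.

## Sign-adjusted FDR, threshold selection, q-values

Genes are partitioned by the tail they favor upon rejection: the sign set
$S$ collects genes with $\tilde\omega_{1g} \ge \tilde\omega_{2g}$
(ties to $S$). A discovery is only credited when its effect's true sign
matches its set, which defines the sign-adjusted FDR. The plug-in
estimator for the rule "reject when $\mathrm{BCR} < \lambda$" is

$$\widehat{\mathrm{mSFDR}}(\lambda) =
 \frac{\sum_{g:\ \mathrm{BCR}_g<\lambda} \tilde\omega_{0g}}
      {\sum_{g\in S:\ \mathrm{BCR}_g<\lambda} \tilde\omega_{1g}
      +\sum_{g\notin S:\ \mathrm{BCR}_g<\lambda} \tilde\omega_{2g}}.$$

The expectation the estimator unbiasedly targets has denominator terms
$E\,\delta_g I(\omega_g \ne 2)$, whose literal expansion would add
$\tilde\omega_{0g}$ per rejected gene; the default follows the estimator
as stated above, and `denominator = "with_null"` switches to the literal
expansion (slightly more conservative, since the denominator grows).

* **Threshold**: $\lambda^*$ is the *largest* $\lambda$ with
  $\widehat{\mathrm{mSFDR}}(\lambda) < \alpha$. The estimator is piecewise
  constant with breakpoints at the distinct BCR values, so
  `select_lambda()` searches breakpoints exactly — no grid. When every
  gene can be rejected the threshold saturates at $1 - 10^{-9}$; when even
  the smallest nonempty rejection set violates $\alpha$ it falls below
  the minimum BCR and nothing is rejected.
* **q-values**: rank genes by BCR, evaluate the estimator on each nested
  rejection set, and take the running minimum from the bottom
  (the standard q-value monotonization, which the source description
  leaves informal); ties in BCR share a q-value because a BCR threshold
  cannot split them. Raw estimates can exceed 1 (the denominator omits
  $\tilde\omega_0$), so reported q-values are capped at 1.
* **Degenerate cases**: empty rejection set gives estimate 0 (0/0
  convention); a rejected set whose favored-tail mass is all zero while
  null mass is positive returns the sentinel $+\infty$ with a warning. A
  gene with *both* masses zero (possible only in the bivariate model, see
  below) contributes nothing to either side and is nominally rejected at
  zero cost.

## The sampler

A blocked Gibbs sweep per gene, then one global update:

1. $\beta_g \mid \lambda_g, \tau, y_g$ with $c_g$ **and** $\sigma_g^2$
   integrated out — under the normal-inverse-gamma structure this marginal
   conditional is a scaled/shifted Student-t with $2(\xi_1 + n/2)$ degrees
   of freedom. Sampling from the marginal rather than the full conditional
   improves mixing.
2. $\sigma_g^2 \mid \beta_g$ (inverse-gamma, $c_g$ integrated out), then
   $c_g \mid \beta_g, \sigma_g^2$ (normal) — exact conditionals.
3. $\lambda_g$ by slice sampling from
   $\propto (1+\lambda^2)^{-1}\lambda^{-1}
   \exp\{-(\beta_g-h_g)^2/(2\sigma_g^2\lambda^2\tau^2)\}$.
4. One slice update of the global $\tau$, aggregating all genes.

All conditionals were validated against independent oracles before use: a
closed-form conjugate posterior computed by generic matrix algebra, 1-D
quadrature for the slice targets, the half-Cauchy CDF for the prior-only
slice chain, and 95% credible-interval coverage on data generated exactly
from the hierarchical model.

Numerical choices:

* **Slice sampler**: stepping-out plus shrinkage on the log scale, width
  1.0, at most 50 step-outs per side — scale parameters are positive and
  heavy-tailed, so the log scale keeps step sizes commensurate.
* **Floors**: $\lambda, \tau \ge 10^{-6}$. When the Gaussian term
  vanishes (a gene sitting exactly on its prior center) the conditional
  has an improper spike at 0; the floor makes the slice target proper
  while being far below any scale that affects inference.
* **Defaults**: `n_iter = 4000`, `burn_in = 2000`, `thin = 2`
  (1000 retained draws; at least 200 are required so tail probabilities
  are estimable). Initialization: $c_g$ at the gene mean, $\beta_g$ at the
  group-mean difference, $\sigma_g^2$ at the pooled variance,
  $\lambda_g = \tau = 1$.
* **Determinism**: updates are serial over genes and driven by R's RNG;
  `set.seed(settings$seed)` makes runs bit-identical. The per-gene updates
  are conditionally independent given $\tau$, so a parallel variant with
  per-gene substreams is possible, but this version keeps the simpler
  serial contract. `tau_fixed` freezes the global scale for sensitivity
  checks and for oracle validation.
* **Boundary convention**: draws exactly at $\pm\epsilon$ count as tail
  mass (closed tails, open null interval) — measure-zero in theory but
  deterministic in code.

## The two-component single-cell model

Single-cell matrices contain exact zeros (dropouts) that a normal model
cannot describe. Gene $g$ gets a logistic detection component and a
continuous component:

$$\Pr(Z_{ig}=1) = \mathrm{logit}^{-1}(c^D_g + X_i\beta^D_g), \qquad
  Y_{ig}\mid Z_{ig}=1 \sim N(c^C_g + X_i\beta^C_g, \sigma_g^2),$$

with bivariate prior center $h_g = (\kappa\mu_g, \mu_g)$: the continuous
effect shrinks toward the bulk LFC $\mu_g$ and the detection-odds effect
toward $\kappa\mu_g$. The default $\kappa = 1$ assumes detection-odds
changes track expression changes; it is exposed as a parameter (and CLI
flag) because that coupling is an assumption, not a fact.

Design choices where the source structure was open:

* The prior scale for $\beta^D$ is $N(\kappa\mu_g, (\lambda^D_g)^2\tau^2)$
  — its own local scale, the shared global $\tau$, and *no* $\sigma^2$
  factor, because the logistic likelihood has no residual variance. The
  intercept priors are $c^D \sim N(0, 10^2)$ and
  $c^C \sim N(0, 10^2\sigma^2)$.
* The logistic coefficients are updated by adaptive random-walk
  Metropolis: proposal scales tuned toward 44% acceptance with a
  Robbins–Monro schedule during burn-in and frozen afterwards (so the
  post-burn-in chain is a fixed, valid kernel). Pólya-Gamma conditional
  augmentation would be the exact-conditional alternative; the Metropolis
  kernel targets the same posterior and passes the same coverage oracle,
  which is the criterion that matters.
* Genes need at least 3 nonzero cells per group (configurable) to be
  analyzed; below that the continuous effect is not identifiable and the
  gene is skipped with a warning.

The bivariate null region is the rectangle
$(-\epsilon_1,\epsilon_1)\times(-\epsilon_2,\epsilon_2)$ over
$(\beta^D, \beta^C)$, and the four alternative categories require *both*
coordinates beyond their thresholds with sign patterns $(-,-)$, $(+,+)$,
$(-,+)$, $(+,-)$. Draws with one coordinate inside and one outside belong
to no category, so the five probabilities can sum to less than 1; the BCR
denominator discounts the smallest of the four category probabilities,
and the favored category (argmax, ties to the lowest index) generalizes
the sign set. One consequence worth knowing: as $\epsilon_1 \to \infty$
the four categories empty out, so the bivariate test does *not* literally
collapse to a univariate test on $\beta^C$ — the null mass does reduce to
the univariate $\tilde\omega_0$ of $\beta^C$ (asserted in the tests), but
sign bookkeeping requires both coordinates. The faithful reduction to the
univariate model is the no-dropout case $Z \equiv 1$, which the tests
verify distributionally against the univariate sampler.

## What the simulator emulates — and what it does not

`generate_dataset()` reproduces the evaluation scheme: exactly
$\mathrm{round}(G\,p)$ genes are differential (drawn uniformly; a fixed
count, not binomial thinning, so scenario size is exact), their effects
$|\beta| \sim N(\log_2 2,\ 0.1^2)$ with random sign, all other effects 0;
every gene's prior center is perturbed around its truth,
$h_g \sim N(\beta_g, 0.5^2)$ — nulls therefore get $h_g \sim N(0, 0.5^2)$,
the consistent reading when the source specifies the perturbation only
for differential genes; baseline $c = 4$, residual $\sigma = 1$, normal
errors on the log2 scale. A hook for unimodal effect distributions exists
via `de_mean`/`de_sd` but the bimodal two-fold default is the study
condition.

What this does **not** emulate: count-level noise (data are generated
directly on the log scale, so normalization dialects are untested by
simulation), library-size variation, correlated genes, batch effects,
outliers or heavy-tailed residuals, and any misspecification of the prior
table beyond Gaussian perturbation. Passing the simulation checks
therefore demonstrates correctness of the algorithm under its own model
assumptions, and calibration robustness to a prior that is noisy but
unbiased — not robustness to systematically wrong priors or non-normal
data.

Problem sizes used by the checks are deliberate package choices: the
SFDR-control run uses 10 replicates of $G = 500$ genes with 50 samples per
group at $p = 0.5$, $\epsilon = \log_2 1.5$, nominal $\alpha = 0.05$, with
default chain lengths; coverage oracles use $G = 200$ genes (univariate)
and $G = 100$ genes with 200 cells per group (logistic component). These
are large enough that Monte-Carlo bands (2 SE across replicates, 3
binomial SE for coverage) are meaningfully tight.

## Known limitations

* One binary covariate; the conjugate algebra generalizes to $p > 1$ but
  v1 does not expose it.
* The original horseshoe scales are used as-is; regularized variants would
  mitigate the known heavy-tail pathologies when prior and data disagree
  globally.
* $\tau$ is shared across both components of the two-component model; a
  component-specific global scale is a plausible alternative.
* Realized-SFDR guarantees are about the marginal criterion; per-dataset
  false discovery proportions fluctuate, especially with few rejections.
* The mSFDR estimator can exceed 1; q-values are capped, which is a
  reporting convention rather than a property of the estimand.
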