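---
title: "Bayesian CFA validation: models, priors, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian CFA validation: models, priors, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `bayescfa`, the
assumptions baked into each stage of the validation workflow, and the
numerical decisions a user or reviewer may want to audit.

## The factor model and its marginal likelihood

For item responses $y_i \in \mathbb{R}^p$ the model is

$$y_i = \nu + \Lambda \eta_i + \varepsilon_i, \qquad
  \eta_i \sim N_m(0, \Phi), \qquad
  \varepsilon_i \sim N_p(0, \Theta),$$

with $\nu$ the item intercepts, $\Lambda$ a $p \times m$ loading matrix in
which each item loads on exactly one factor (no cross-loadings, no
correlated uniquenesses), $\Theta$ diagonal, and
$\Phi = D \, R \, D$ where $D$ holds the latent standard deviations and $R$
is the factor correlation matrix.  Latent means are fixed at 0, and the
latent scale is set by unit loading identification (ULI): the loading of the
first item of each subscale is fixed to 1 while the factor variances remain
free.  Integrating the latent variables out gives the marginal likelihood,
multivariate normal with mean $\nu$ and covariance
$\Sigma = \Lambda \Phi \Lambda' + \Theta$; `bcfa()` evaluates it from the
sufficient statistics $(\bar y, S, N)$ only, which is what makes repeated
evaluation cheap.  The sample covariance uses divisor $N$ (the ML
convention) so that the $\chi^2$ discrepancy equals
$2(L_\text{sat} - L_\text{model})$ exactly; a divisor of $N-1$ would shift
every discrepancy by $O(p^2)$.

## Priors

The prior set is the vague default conventional for Bayesian SEM with
continuous indicators:

| parameter               | prior                         | default    |
|-------------------------|-------------------------------|------------|
| free loadings           | $N(0, 100)$                   |            |
| intercepts              | $N(0, 1024)$                  |            |
| residual SDs            | $\text{Gamma}(1, \text{rate } 0.5)$ (mean 2) | |
| latent SDs              | $\text{Gamma}(1, \text{rate } 0.5)$          | |
| factor correlations     | uniform on $[-1,1]$ per off-diagonal, jointly truncated to positive definite $R$ | |

Two details deserve attention.  First, the Gamma(1, 0.50) prior is
interpreted as shape 1 and *rate* 0.5 (prior mean 2), the convention of the
reference software family this prior set comes from.  Second, the
correlation prior is the per-correlation-uniform density restricted to the
positive definite region.  For $m \le 2$ the restriction is vacuous; for
$m = 3$ the support is the elliptope with volume $\pi^2/2$, and the package
uses that exact normalizing constant in the joint prior density.  This
matters only for marginal-likelihood comparisons between models with
different numbers of correlation parameters; omitting the constant would
bias the Bayes factors by a few tenths of a log unit.  A side effect of the
truncation is that each correlation's *marginal* prior is not exactly
uniform: for $m = 3$ it is Beta(1.5, 1.5)-shaped on $[-1, 1]$ (mean 0,
standard deviation 0.5).  The prior-sampling tests assert those moments
rather than pretending the marginal is uniform.

## The sampler

The posterior is sampled with an adaptive random-walk
Metropolis-within-Gibbs kernel implemented in C++, on unconstrained
transforms: log standard deviations and $\text{atanh}$ correlations, with
the transform Jacobians carried in the target density.  Three design
choices:

* **Intercepts are updated by an exact Gibbs draw.**  Given the implied
  covariance, $\nu$ has a conjugate multivariate normal conditional.
  Because the implied inter-item correlations are high (about 0.84 for the
  strongest pairs at the default generating parameters), single-site
  random-walk updates of $\nu$ mix an order of magnitude more slowly than
  everything else; the conjugate block draw removes that bottleneck
  entirely.
* **One recorded iteration is several full coordinate scans** (`sweeps`,
  default 8).  The remaining 27 covariance-side coordinates (for the
  three-factor model) are updated one at a time with normal proposals whose
  log-scales adapt during warmup toward a 0.44 acceptance rate
  (Robbins–Monro, step $\min(0.25, 2/\sqrt{t})$) and are frozen when warmup
  ends, so the kept draws come from a fixed kernel.
* **Seeding:** the master seed initializes R's RNG, which draws one
  independent seed per chain; each chain then runs from its own stream.
  Identical inputs give byte-identical draws.

The default chain protocol is 3 chains with 1000 kept iterations after 1000
warmup iterations each.  Convergence is reported per parameter via the
(unsplit) Gelman–Rubin PSRF across chains, flagged at 1.1, and the batch
means Monte Carlo standard error on the pooled draws (batch size
$\lfloor\sqrt{s}\rfloor$), flagged at 5% of the posterior standard
deviation.  With the default protocol on the package's reference fixture
(n = 3868, three-factor structure) the PSRFs are below 1.01 and every MCSE
is below 4% of its posterior SD.  Non-convergence produces a warning and a
flag, never a silent result.

## Posterior predictive fit assessment

The discrepancy is the likelihood-ratio $\chi^2$
$$\chi^2 = N\left[\log|\hat\Sigma| - \log|S| +
  \operatorname{tr}(S\hat\Sigma^{-1}) - p +
  (\bar y - \hat\mu)'\hat\Sigma^{-1}(\bar y - \hat\mu)\right].$$

For every kept draw, `posterior_predictive()` computes the observed-data
discrepancy and the discrepancy of a *full replicate dataset* of size $N$
simulated from the model at that draw (not a $\chi^2$-distribution
shortcut), and reports $\text{PPP} = \Pr(D^{rep} > D^{obs})$.  Verbal
definitions of PPP in the applied literature sometimes state the opposite
inequality; this package uses the direction under which a well-specified
model yields PPP $\approx 0.5$ and gross misfit yields PPP $\approx 0$,
which matches how reported values behave and how the reference software
defines it.

The effective number of parameters is the marginalized-DIC quantity
$p_D = \overline{D(\theta)} - D(\bar\theta)$ with
$D(\theta) = -2\,\log L(\theta)$ on the latent-integrated likelihood and
$\bar\theta$ the posterior mean taken on the natural parameter scale
(intercepts, loadings, residual variances, latent SDs, correlations).
Under the vague priors above, $p_D$ lands within a few units of the free
parameter count (39 for the three-factor model).

Per-iteration fit indices are
$$\text{BRMSEA}_i = \sqrt{\frac{\max(0,\, D_i^{obs} - p^*)}{(p^* - p_D)\,N}},
\qquad
\text{BCFI}_i = 1 - \frac{\max(0,\, D_{H,i}^{obs} - p^*)}
                          {\max(\epsilon,\, D_{0,i}^{obs} - p^*)},$$

with $p^* = p(p+3)/2$ the number of unique sample moments (90 for 12
items) and $D_0$ the discrepancy of an independence model (diagonal
covariance, free means and variances) fitted with the same chain protocol
so iterations pair one-to-one.  The square root in BRMSEA and the flooring
and capping in BCFI follow the frequentist conventions for RMSEA/CFI; the
square-root form is the one that reproduces published three-decimal BRMSEA
values from their printed $\chi^2$ and $p_D$ inputs.  Both indices are
summarized by posterior means and central 90% intervals.  Cutoff-based
hypothesis testing on these indices is deliberately not provided; they are
descriptive measures of approximation error.

## Model comparison

Marginal likelihoods are approximated by the Laplace method at the
posterior mode: BFGS quasi-Newton from five jittered starts on the
unconstrained scale, then
$\log \hat m = \log p(y, \hat u) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log |H|$ with $H$ the negative-log-posterior Hessian from
symmetric central differences (relative step $10^{-4}$).  The
approximation is taken on the unconstrained scale with Jacobian-corrected
densities; it is exact for Gaussian posteriors (the package tests it
against the closed-form conjugate normal-mean marginal) and accurate for
the large-$n$, near-Gaussian posteriors this workflow produces (independent
restarts agree to well under 0.1 log units).  Bayes factors are reported on
the natural-log and log10 scales because realistic magnitudes here
(hundreds to thousands of log10 units) overflow any direct ratio.

## Reliability

Subscale reliability is McDonald's $\omega_H$,
$$\omega_H = \frac{(\sum_j \lambda_j)^2 \psi}
  {(\sum_j \lambda_j)^2 \psi + \sum_j \theta_j},$$
evaluated at every kept draw of the standardized solution ($\psi = 1$),
which yields a posterior distribution of reliability summarized by its mean
and central 95% interval.  The statistic is invariant to the latent scale
convention — the ULI solution (free factor variance) and the
standardized-factor solution give identical $\omega_H$, since the loadings
absorb $\sqrt\psi$ — and the package asserts this algebraically per draw.
It is *not* invariant to rescaling individual items, so the package
evaluates it on the completely standardized solution throughout, the
convention under which published subscale reliabilities are computed from
standardized parameter tables.  Printed formulas for
"Bayesian omega" in the applied literature sometimes mangle the denominator
typographically; the form above is the standard model-based $\omega_H$ and
is the one that reproduces published two-decimal subscale reliabilities
from their own printed standardized solutions.  Credible intervals are
equal-tailed; nothing here suggests HPD intervals, and the package reflects
only parameter-posterior uncertainty (no extra sampling variability).

## Criterion validity

Associations between subscale total scores (sum of the factor's four
items; missing if any item is missing) and external criterion scores use
Kendall's $\tau_b$, the tie-corrected variant — Likert totals are heavily
tied — on pairwise-complete observations.  The Bayesian machinery follows
the parametric-yoking construction for rank correlations: the standardized
statistic $T^* = 3\tau_b\sqrt{n(n-1)}/\sqrt{2(2n+5)}$ is asymptotically
$N(1.5\,\tau\sqrt n, 1)$, which combined with a uniform prior on $[-1,1]$
gives a posterior for $\tau$ evaluated on a 4001-point grid; the Bayes
factor for a nonzero association is the Savage–Dickey density ratio at
$\tau = 0$, computed in log space so that evidence of order $10^{80}$
remains finite.  The point estimate $\tau_b$ itself is delegated to
`stats::cor(method = "kendall")`; the test suite checks it against an
$O(n^2)$ pair-enumeration oracle, ties included.

## The synthetic-data generator

The generator emulates the survey conditions the workflow is designed for:
n = 3868 complete cases on 12 five-point items in three four-item
subscales, standardized loadings between 0.82 and 0.94, factor
correlations 0.505–0.636, raw-scale intercepts 3.88–4.55, and per-item
MCAR missingness spread linearly over 0.02%–0.18% (at survey scale that is
roughly one to seven missing cells per item).  Responses are built as
$y = \nu + D(\Lambda^* \eta + \varepsilon)$ from the standardized latent
structure, so the population correlation matrix reproduces the published
standardized solution exactly; $D$ holds raw item SDs, which default to 1
because raw SDs were not published — an assumption, not an inference.

Likert mode rounds to the nearest integer and clips to $[1, 5]$.  This
round-and-clip discretization is deliberately simple: it preserves rank
structure but attenuates standardized loadings and shrinks item means
toward the scale midpoint, which is why the recovery checks use continuous
mode — the fitted model is a mean-structure (continuous) CFA, and
continuous mode is the regime in which it is correctly specified.  What
passing tests therefore demonstrate is recovery and calibration *under the
model's own assumptions*; they do not certify behavior under ordinal
measurement, non-MCAR missingness, response styles, or item parameter
drift, none of which the generator emulates.

## Problem sizes and tolerances in the test suite

The test suite exercises the full chain protocol (3 × 1000 + 1000) on one
n = 3868 fixture shared across checks, and uses reduced protocols
(2 chains, 300–400 kept, 4–6 sweeps) for replication studies: 20
replications at n = 500 for PPP calibration (mean PPP asserted in
[0.3, 0.7]) and 20 replications at n = 1000 for 95% interval coverage of
loadings and correlations (asserted at or above 0.88, the lower edge of a
binomial band that accounts for within-replication dependence).  Identity
checks ($\chi^2$ versus twice the log-likelihood gap) are asserted at
$10^{-8}$; parameter recovery at n = 3868 at ±0.02; the
posterior-mean-versus-ML agreement at ±0.01 per standardized parameter.
The degenerate cases each operation must handle — non-positive-definite
correlation proposals (rejected via $-\infty$, not exceptions), singular
sample covariances (warned), constant score vectors (error), empty
complete-case sets (error) — are pinned by dedicated tests.

## Known limitations

* Ordinal (threshold-structure) factor models are out of scope; the
  continuous treatment of 5-point items is an approximation whose fit
  indices are the ones validated for mean-structure models.
* The Laplace approximation can be optimistic for small samples or
  near-boundary modes (e.g. correlations near ±1); bridge sampling would
  be the upgrade path.
* The Kendall posterior relies on the asymptotic normality of $T^*$;
  below a few dozen pairs the exact permutation distribution would be
  preferable.
* Missingness handling is complete-case only, appropriate for the
  per-mille missingness regime the generator emulates, not for
  substantial or informative missingness.
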