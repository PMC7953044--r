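# bayescfa

Bayesian confirmatory factor analysis (CFA) for instrument validation, with
posterior predictive fit assessment, Bayes-factor dimensionality testing,
posterior reliability, and Bayesian rank-correlation criterion validity.

The package is built for the workflow used to validate multi-subscale
questionnaires such as the 12-item Multidimensional Scale of Perceived
Social Support (MSPSS: Significant Other, Family, and Friends subscales of
four 5-point items each): fit competing factorial structures, judge each
one's fit from the posterior, test dimensionality formally, and report
subscale reliability and criterion validity — all within one Bayesian
framework.  Because the survey data such studies use are typically not
redistributable, the package ships a synthetic-data generator
parameterized by published estimates, so the entire workflow runs and is
tested end-to-end without any external data.

## The model and the statistics it reports

Item responses follow the linear factor model
*y*ᵢ = ν + Λ ηᵢ + εᵢ with ηᵢ ~ N(0, Φ), εᵢ ~ N(0, Θ), each item loading
on one factor, latent scale set by fixing the first loading per factor to 1
(ULI).  Inference uses the *marginal* likelihood — multivariate normal with
covariance ΛΦΛ′ + Θ after integrating out η — under vague priors:
N(0, 100) loadings, N(0, 1024) intercepts, Gamma(1, rate 0.5) residual and
latent SDs, and per-correlation uniform[−1, 1] priors truncated to positive
definite correlation matrices.  Sampling is an adaptive
Metropolis-within-Gibbs kernel (C++), 3 chains × 1000 kept after 1000
warmup by default, with Gelman–Rubin PSRF and batch-means MCSE diagnostics.

On top of a fitted model the package computes:

* **PPP(χ²)** — posterior predictive p-value of the likelihood-ratio
  discrepancy χ² = N[log|Σ̂| − log|S| + tr(SΣ̂⁻¹) − p + (ȳ−μ̂)′Σ̂⁻¹(ȳ−μ̂)],
  with a full replicate dataset simulated per draw; ≈ 0.5 means the data
  look like the model's own replicates, ≈ 0 means misfit.
* **BRMSEA and BCFI** — per-iteration Bayesian analogues of RMSEA/CFI,
  BRMSEA = √(max(0, D − p\*) / ((p\* − pD)·N)) and
  BCFI = 1 − max(0, D_H − p\*)/(D₀ − p\*), using the effective number of
  parameters pD from the marginalized DIC and an independence-model
  baseline fitted with the same protocol.
* **Bayes factors** — Laplace-approximation marginal likelihoods at the
  posterior mode, reported on the log10 scale (realistic magnitudes
  overflow direct ratios).
* **BΩ_H** — McDonald's omega-H, (Σλ)²ψ / ((Σλ)²ψ + Σθ), evaluated at
  every posterior draw to give a reliability posterior per subscale.
* **Bayesian Kendall's τ-b** — rank correlations of subscale totals with
  external criteria, uniform[−1, 1] prior, Savage–Dickey BF₁₀.

## Worked example

```r
library(bayescfa)

## 1200 synthetic 5-point responses from the published three-factor solution
y   <- generate_responses(mspss_parameters(), n = 1200, mode = "likert",
                          seed = 1)
fit <- bcfa(y, mspss_spec("three"), n_chains = 3, n_warmup = 500,
            n_kept = 500, sweeps = 6, seed = 2)
fit
#> Bayesian CFA fit 
#>   model: 3-factor (SO, FA, FR);  items: 12;  N = 1200
#>   chains: 3 x 500 kept after 500 warmup (6 sweeps/iteration)
#>   max PSRF: 1.003  (converged)

s <- summary(fit)   # completely standardized solution
s$table[s$table$parameter %in%
          c("lambda_std[q1]", "corr[SO,FA]", "corr[SO,FR]"), ]
#>       parameter      mean     ci_lo     ci_hi      psrf
#>  lambda_std[q1] 0.8502048 0.8307445 0.8683759 1.0000096
#>     corr[SO,FA] 0.6577538 0.6202226 0.6954703 1.0004425
#>     corr[SO,FR] 0.4765303 0.4270882 0.5223336 0.9990818

fit_indices(fit, seed = 3, label = "three-factor")
#> Posterior fit assessment - three-factor 
#>         model chisq_mean     pD     df   ppp brmsea_mean brmsea_lo90
#>  three-factor     103.38 38.722 51.278 0.214    0.013823   0.0033807
#>  brmsea_hi90 bcfi_mean bcfi_lo90 bcfi_hi90
#>     0.021399   0.99866    0.9972   0.99993

omega_posterior(fit, "SO")
#> omega-H (SO): 0.92 - 95% CrI (0.91, 0.93)
```

Reading the output: the sampler converged (every PSRF ≤ 1.003); the
standardized loadings and factor correlations sit near their generating
values (5-point discretization attenuates loadings slightly — 0.85
recovered from a generating 0.898 — which is why exact-recovery checks use
continuous mode); PPP = 0.21 with BRMSEA ≈ 0.01 and BCFI ≈ 0.999 says the
three-factor model reproduces its own data, and pD ≈ 38.7 is close to the
39 free parameters, as vague priors imply; the SO subscale's reliability
posterior is centered at 0.92.

The staged validation — one-factor first, then the three two-factor
collapses, then the three-factor model, with a shared independence
baseline, Bayes-factor comparison, reliability and (optionally) criterion
validity — is one call:

```r
pl <- run_validation_pipeline(n = 3868, seed = 1)
pl$fit_table      # one row per structure, in evaluation order
pl$selected       # best-supported structure by log marginal likelihood
```

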