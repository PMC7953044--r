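#' Prior settings for Bayesian CFA
#'
#' The vague prior set conventional for Bayesian structural equation models
#' with continuous indicators: normal priors on free loadings and intercepts,
#' Gamma(shape, rate) priors on residual and latent standard deviations
#' (shape 1, rate 0.5 gives prior mean 2), and a per-correlation uniform
#' prior on \[-1, 1\] jointly truncated to positive definite correlation
#' matrices.
#'
#' @param loading_var Prior variance of free loadings (mean 0); default 100.
#' @param intercept_var Prior variance of intercepts (mean 0); default 1024.
#' @param resid_sd_shape,resid_sd_rate Gamma shape and rate for residual
#'   standard deviations; default shape 1, rate 0.5.
#' @param factor_sd_shape,factor_sd_rate Gamma shape and rate for latent
#'   standard deviations; default shape 1, rate 0.5.
#' @return Object of class `cfa_priors`.
#' @export
cfa_priors <- function(loading_var = 100, intercept_var = 1024,
                       resid_sd_shape = 1, resid_sd_rate = 0.5,
                       factor_sd_shape = 1, factor_sd_rate = 0.5) {
  stopifnot(loading_var > 0, intercept_var > 0,
            resid_sd_shape > 0, resid_sd_rate > 0,
            factor_sd_shape > 0, factor_sd_rate > 0)
  structure(list(loading_var = loading_var, intercept_var = intercept_var,
                 resid_sd_shape = resid_sd_shape, resid_sd_rate = resid_sd_rate,
                 factor_sd_shape = factor_sd_shape,
                 factor_sd_rate = factor_sd_rate),
            class = "cfa_priors")
}

#' @export
print.cfa_priors <- function(x, ...) {
  cat("CFA priors:\n",
      "  loadings    ~ N(0, ", x$loading_var, ")\n",
      "  intercepts  ~ N(0, ", x$intercept_var, ")\n",
      "  residual SD ~ Gamma(", x$resid_sd_shape, ", rate ", x$resid_sd_rate,
      ")\n",
      "  factor SD   ~ Gamma(", x$factor_sd_shape, ", rate ", x$factor_sd_rate,
      ")\n",
      "  correlations ~ uniform on [-1, 1], jointly truncated to PD\n",
      sep = "")
  invisible(x)
}

# prior list handed to the C++ routines
priors_as_list <- function(priors) {
  list(loading_sd = sqrt(priors$loading_var),
       nu_sd = sqrt(priors$intercept_var),
       resid_shape = priors$resid_sd_shape, resid_rate = priors$resid_sd_rate,
       fsd_shape = priors$factor_sd_shape, fsd_rate = priors$factor_sd_rate)
}

#' Log prior density of a parameter point
#'
#' Sum of the independent log prior densities over the free parameters of the
#' model, on the natural parameter scale (no transform Jacobians): free
#' loadings, intercepts, residual SDs (the square roots of `theta`), factor
#' SDs, and the factor correlations (constant density on the positive
#' definite region).  Returns `-Inf` outside the support (a non-positive
#' definite correlation matrix or non-positive SDs), never an error.
#'
#' @param params A [cfa_parameters()] object.
#' @param priors A [cfa_priors()] object.
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, priors = cfa_priors()) {
  stopifnot(inherits(params, "cfa_parameters"), inherits(priors, "cfa_priors"))
  spec <- params$spec
  if (any(params$theta <= 0) ||
      (spec$m > 0 && any(params$factor_sd <= 0))) return(-Inf)
  lp <- sum(stats::dnorm(params$nu, 0, sqrt(priors$intercept_var), log = TRUE))
  lp <- lp + sum(stats::dgamma(sqrt(params$theta), priors$resid_sd_shape,
                               rate = priors$resid_sd_rate, log = TRUE))
  if (spec$m > 0) {
    free <- !spec$is_ref
    lp <- lp + sum(stats::dnorm(params$lambda[free], 0,
                                sqrt(priors$loading_var), log = TRUE))
    lp <- lp + sum(stats::dgamma(params$factor_sd, priors$factor_sd_shape,
                                 rate = priors$factor_sd_rate, log = TRUE))
    if (spec$m > 1) {
      R <- params$factor_corr
      rho <- R[lower.tri(R)]
      if (any(abs(rho) >= 1)) return(-Inf)
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) return(-Inf)
      lp <- lp - log(corr_prior_volume(spec$m))
    }
  }
  lp
}

# Normalizing volume of the PD-truncated per-correlation-uniform prior.
# Exact for m <= 3 (any single correlation in (-1,1) is PD; the 3x3
# elliptope has volume pi^2/2); for larger m the untruncated cube volume is
# used, which cancels in Bayes factors between models of equal m.
corr_prior_volume <- function(m) {
  ncorr <- m * (m - 1) / 2
  if (m <= 2) 2^ncorr else if (m == 3) pi^2 / 2 else 2^ncorr
}
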