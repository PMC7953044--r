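#' Chi-square discrepancy between sample and model-implied moments
#'
#' `N [ log|Sigma| - log|S| + tr(S Sigma^-1) - p +
#' (ybar - mu)' Sigma^-1 (ybar - mu) ]`, the likelihood-ratio discrepancy of
#' the model against the saturated model; it equals
#' `2 (L_sat - L_model)` exactly under the divisor-`N` covariance convention.
#'
#' @param sm A [sample_moments()] object.
#' @param im Implied moments, a list with `mu` and `sigma` (see
#'   [implied_moments()]).
#' @return Scalar discrepancy (0 for the saturated model).
#' @export
chisq_discrepancy <- function(sm, im) {
  stopifnot(inherits(sm, "sample_moments"))
  R <- tryCatch(chol(im$sigma), error = function(e)
    stop("model-implied covariance is not positive definite"))
  logdet_sigma <- 2 * sum(log(diag(R)))
  logdet_S <- determinant(sm$S, logarithm = TRUE)$modulus
  if (!is.finite(logdet_S)) stop("sample covariance is singular")
  tr <- sum(diag(chol2inv(R) %*% sm$S))
  dv <- backsolve(R, sm$ybar - im$mu, transpose = TRUE)
  as.numeric(sm$N * (logdet_sigma - logdet_S + tr - sm$p + sum(dv^2)))
}

#' Bayesian RMSEA realization
#'
#' Per-iteration Bayesian root mean square error of approximation:
#' `sqrt( max(0, D_obs - p_star) / ((p_star - pD) N) )`, where `p_star` is
#' the number of unique sample moments and `pD` the effective number of
#' parameters.
#'
#' @param d_obs Observed-data chi-square discrepancy (scalar or vector of
#'   per-iteration realizations).
#' @param p_star Number of unique sample moments, `p (p + 3) / 2`.
#' @param pD Effective number of parameters.
#' @param N Sample size.
#' @return BRMSEA value(s), floored at 0.
#' @examples
#' brmsea(17344.41, p_star = 90, pD = 35.78, N = 3868)  # 0.287
#' @export
brmsea <- function(d_obs, p_star, pD, N) {
  if (p_star <= pD)
    stop("p_star must exceed pD (negative effective degrees of freedom)")
  sqrt(pmax(0, d_obs - p_star) / ((p_star - pD) * N))
}

#' Bayesian CFI realization
#'
#' Per-iteration Bayesian comparative fit index:
#' `1 - max(0, D_H - p_star) / max(eps, D_0 - p_star)` with `D_H` the
#' hypothesized-model and `D_0` the independence-model observed-data
#' discrepancy at the same iteration; capped to \[0, 1\].
#'
#' @param d_obs_h Hypothesized-model discrepancy realization(s).
#' @param d_obs_0 Independence-model discrepancy realization(s), paired by
#'   iteration.
#' @param p_star Number of unique sample moments.
#' @return BCFI value(s) in \[0, 1\].
#' @export
bcfi <- function(d_obs_h, d_obs_0, p_star) {
  num <- pmax(0, d_obs_h - p_star)
  den <- pmax(.Machine$double.eps, d_obs_0 - p_star)
  pmin(pmax(1 - num / den, 0), 1)
}

#' Effective number of parameters (marginalized DIC)
#'
#' `pD = mean_i D(theta_i) - D(theta_bar)` with deviance
#' `D(theta) = -2 * marginal_loglik(theta)` (latent variables integrated
#' out) and `theta_bar` the posterior mean of each parameter on its natural
#' scale.  Under vague priors pD approximates the free-parameter count.
#'
#' @param fit A [bcfa()] fit.
#' @return Scalar pD.
#' @export
effective_parameters <- function(fit) {
  stopifnot(inherits(fit, "bcfa"))
  pool <- pooled_draws(fit)
  dev <- apply(pool, 1, function(v)
    -2 * marginal_loglik(row_to_params(v, fit$spec), fit$moments))
  dev_at_mean <- -2 * marginal_loglik(posterior_mean_parameters(fit),
                                      fit$moments)
  mean(dev) - dev_at_mean
}

#' Posterior predictive model check with the chi-square discrepancy
#'
#' For every kept draw, computes the observed-data discrepancy `D_obs` and
#' the discrepancy `D_rep` of a full replicate dataset of size `N` simulated
#' from the model at that draw, then the posterior predictive p-value
#' `PPP = Pr(D_rep > D_obs)`.  A well-specified model gives PPP near 0.5;
#' values near 0 signal misfit.
#'
#' @param fit A [bcfa()] fit.
#' @param seed Optional integer seed for the replicate simulation.
#' @param thin Keep every `thin`-th draw (default 1 = all draws).
#' @return List with vectors `d_obs`, `d_rep` and scalar `ppp`.
#' @export
posterior_predictive <- function(fit, seed = NULL, thin = 1) {
  stopifnot(inherits(fit, "bcfa"))
  if (!is.null(seed)) set.seed(seed)
  pool <- pooled_draws(fit)
  idx <- seq(1, nrow(pool), by = thin)
  if (length(idx) == 0) stop("no kept iterations")
  sm <- fit$moments
  d_obs <- d_rep <- numeric(length(idx))
  for (k in seq_along(idx)) {
    params <- row_to_params(pool[idx[k], ], fit$spec)
    im <- implied_moments(params)
    d_obs[k] <- chisq_discrepancy(sm, im)
    rep_mom <- cpp_sim_moments(im$mu, im$sigma, sm$N)
    rep_sm <- structure(list(ybar = as.numeric(rep_mom$ybar), S = rep_mom$S,
                             N = sm$N, p = sm$p, p_star = sm$p_star),
                        class = "sample_moments")
    d_rep[k] <- chisq_discrepancy(rep_sm, im)
  }
  list(d_obs = d_obs, d_rep = d_rep, ppp = mean(d_rep > d_obs))
}

#' Fit an independence (baseline) model
#'
#' Refits the same data with all inter-item covariances constrained to zero
#' (free means and variances only), with the same chain protocol as `fit`,
#' so iterations pair one-to-one for the comparative fit index.
#'
#' @param fit A [bcfa()] fit providing the data and chain settings.
#' @param seed Integer seed (defaults to the original seed + 1).
#' @return A [bcfa()] fit of the independence model.
#' @export
fit_independence <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "bcfa"))
  spec0 <- cfa_spec(list(), item_names = fit$spec$item_names)
  bcfa(moments = fit$moments, spec = spec0, priors = fit$priors,
       n_chains = fit$n_chains, n_warmup = fit$n_warmup,
       n_kept = fit$n_kept, sweeps = fit$sweeps,
       seed = if (is.null(seed)) fit$seed + 1L else seed)
}

#' Posterior fit assessment (PPP, pD, BRMSEA, BCFI)
#'
#' Runs the posterior predictive check, computes the effective number of
#' parameters from the marginalized deviance, and forms the per-iteration
#' BRMSEA and BCFI realizations (the latter against an independence-model
#' fit with matching protocol, fitted on demand).
#'
#' @param fit A [bcfa()] fit of the hypothesized model.
#' @param independence Optionally a precomputed [fit_independence()] result
#'   (reusable across several hypothesized models on the same data).
#' @param seed Optional integer seed for replicate simulation (and the
#'   independence fit when it is created here).
#' @param label Model label used in the summary row.
#' @return Object of class `bcfa_fit_indices` with fields `d_obs`, `d_rep`,
#'   `ppp`, `pD`, `df`, `brmsea`, `bcfi` (per-iteration realizations),
#'   `p_star`, `N`, `label`, and `independence` (the baseline fit).
#' @export
fit_indices <- function(fit, independence = NULL, seed = NULL,
                        label = NULL) {
  stopifnot(inherits(fit, "bcfa"))
  if (is.null(label))
    label <- if (fit$spec$m == 0) "independence" else
      paste0(fit$spec$m, "-factor")
  pp <- posterior_predictive(fit, seed = seed)
  d_at_mean <- chisq_discrepancy(fit$moments,
                                 implied_moments(posterior_mean_parameters(fit)))
  pD <- mean(pp$d_obs) - d_at_mean
  p_star <- fit$moments$p_star
  if (is.null(independence)) {
    independence <- fit_independence(fit,
                                     seed = if (is.null(seed)) NULL
                                            else seed + 1L)
  } else {
    stopifnot(inherits(independence, "bcfa"),
              independence$spec$m == 0,
              independence$n_kept == fit$n_kept,
              independence$n_chains == fit$n_chains)
  }
  pool0 <- pooled_draws(independence)
  d_obs_0 <- apply(pool0, 1, function(v) {
    chisq_discrepancy(fit$moments,
                      implied_moments(row_to_params(v, independence$spec)))
  })
  structure(list(d_obs = pp$d_obs, d_rep = pp$d_rep, ppp = pp$ppp,
                 pD = pD, df = p_star - pD,
                 brmsea = brmsea(pp$d_obs, p_star, pD, fit$moments$N),
                 bcfi = bcfi(pp$d_obs, d_obs_0, p_star),
                 d_obs_0 = d_obs_0,
                 chisq_mean = mean(pp$d_obs),
                 p_star = p_star, N = fit$moments$N, label = label,
                 independence = independence),
            class = "bcfa_fit_indices")
}

#' @export
print.bcfa_fit_indices <- function(x, digits = 3, ...) {
  cat("Posterior fit assessment -", x$label, "\n")
  print(summarize_fit(x), row.names = FALSE, digits = digits + 2)
  invisible(x)
}

#' Summarize posterior fit indices as a table row
#'
#' Emits the posterior-mean chi-square, pD, effective degrees of freedom
#' (`p_star - pD`), PPP, and the posterior means with central 90% credible
#' intervals of BRMSEA and BCFI.
#'
#' @param fi A [fit_indices()] result.
#' @return One-row data frame.
#' @export
summarize_fit <- function(fi) {
  stopifnot(inherits(fi, "bcfa_fit_indices"))
  q <- function(v) stats::quantile(v, c(0.05, 0.95), names = FALSE)
  br <- q(fi$brmsea); bc <- q(fi$bcfi)
  data.frame(model = fi$label,
             chisq_mean = fi$chisq_mean, pD = fi$pD, df = fi$df,
             ppp = fi$ppp,
             brmsea_mean = mean(fi$brmsea),
             brmsea_lo90 = br[1], brmsea_hi90 = br[2],
             bcfi_mean = mean(fi$bcfi),
             bcfi_lo90 = bc[1], bcfi_hi90 = bc[2],
             row.names = NULL)
}
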