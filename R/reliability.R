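#' McDonald's omega-H from factor model parameters
#'
#' Model-based subscale reliability: the proportion of total-score variance
#' attributable to the common factor,
#' `omega = (sum lambda)^2 psi / ((sum lambda)^2 psi + sum theta)`,
#' where `psi` is the factor variance.  On the completely standardized
#' solution `psi = 1`.  The value is invariant to the standardization
#' convention because numerator and denominator rescale together.
#'
#' @param loadings Numeric vector of the subscale's loadings (k >= 2).
#' @param residual_variances Numeric vector of the subscale's residual
#'   variances.
#' @param factor_variance Factor variance `psi` (default 1, the
#'   standardized convention).
#' @return Scalar omega in \[0, 1\].
#' @examples
#' omega_h(c(0.898, 0.936, 0.908, 0.873),
#'         c(0.194, 0.124, 0.176, 0.238))  # 0.947
#' @export
omega_h <- function(loadings, residual_variances, factor_variance = 1) {
  stopifnot(length(loadings) >= 2,
            length(residual_variances) == length(loadings),
            all(residual_variances > 0), factor_variance > 0)
  common <- sum(loadings)^2 * factor_variance
  common / (common + sum(residual_variances))
}

#' Posterior distribution of subscale reliability
#'
#' Applies the omega-H formula to every kept draw of a fitted model (on its
#' completely standardized solution), yielding a posterior distribution of
#' the subscale's reliability.
#'
#' @param fit A [bcfa()] fit with at least one factor.
#' @param subscale Factor label (one of `fit$spec$factor_names`).
#' @param level Credible level for the central interval (default 0.95).
#' @return Object of class `omega_posterior` with `draws`, `mean`, `ci`,
#'   and `subscale`.
#' @export
omega_posterior <- function(fit, subscale, level = 0.95) {
  stopifnot(inherits(fit, "bcfa"), fit$spec$m > 0)
  if (!subscale %in% fit$spec$factor_names)
    stop("unknown subscale '", subscale, "'; available: ",
         paste(fit$spec$factor_names, collapse = ", "))
  std <- pool_array(standardized_draws(fit))
  items <- fit$spec$factors[[subscale]]
  lam <- std[, paste0("lambda_std[", items, "]"), drop = FALSE]
  th <- std[, paste0("theta_std[", items, "]"), drop = FALSE]
  draws <- rowSums(lam)^2 / (rowSums(lam)^2 + rowSums(th))
  a <- (1 - level) / 2
  structure(list(draws = draws, mean = mean(draws),
                 ci = stats::quantile(draws, c(a, 1 - a), names = FALSE),
                 level = level, subscale = subscale),
            class = "omega_posterior")
}

#' @export
print.omega_posterior <- function(x, digits = 2, ...) {
  cat(sprintf("omega-H (%s): %.*f - %.0f%% CrI (%.*f, %.*f)\n",
              x$subscale, digits, x$mean, 100 * x$level,
              digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' Reliability report for every subscale
#'
#' @param fit A [bcfa()] fit.
#' @param level Credible level (default 0.95).
#' @return Data frame with one row per factor: posterior mean and central
#'   credible interval of omega-H.
#' @export
reliability_report <- function(fit, level = 0.95) {
  rows <- lapply(fit$spec$factor_names, function(f) {
    om <- omega_posterior(fit, f, level = level)
    data.frame(subscale = f, omega_mean = om$mean,
               ci_lo = om$ci[1], ci_hi = om$ci[2], row.names = NULL)
  })
  do.call(rbind, rows)
}
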