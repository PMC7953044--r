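#' Maximum a posteriori estimate
#'
#' Maximizes the unnormalized log posterior (marginal log-likelihood plus
#' log prior, with transform Jacobians) over the unconstrained parameter
#' scale by quasi-Newton (BFGS) from several jittered starts, returning the
#' best mode found.
#'
#' @param moments A [sample_moments()] object.
#' @param spec A [cfa_spec()].
#' @param priors A [cfa_priors()] object.
#' @param n_starts Number of jittered starts (default 5).
#' @param seed Optional integer seed for the start jitter.
#' @return List with `params` (a [cfa_parameters()] point), `u` (the
#'   unconstrained mode), `logpost` (value at the mode), and `converged`.
#' @export
map_estimate <- function(moments, spec, priors = cfa_priors(), n_starts = 5,
                         seed = NULL) {
  stopifnot(inherits(moments, "sample_moments"), inherits(spec, "cfa_spec"))
  if (!is.null(seed)) set.seed(seed)
  prior_list <- priors_as_list(priors)
  fn <- function(u) {
    lp <- cpp_log_posterior(u, moments$S, moments$ybar, moments$N, spec$p,
                            spec$m, as.integer(spec$factor_of), spec$is_ref,
                            prior_list, 1)
    if (!is.finite(lp)) 1e12 else -lp
  }
  u0 <- moment_start(moments, spec)
  best <- NULL
  any_ok <- FALSE
  for (s in seq_len(n_starts)) {
    us <- if (s == 1) u0 else u0 + stats::rnorm(length(u0), 0, 0.2)
    opt <- tryCatch(
      stats::optim(us, fn, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e11) next
    any_ok <- any_ok || opt$convergence == 0
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !any_ok)
    stop("MAP optimization failed to converge from all starts")
  u_nat <- stats::setNames(
    drop(u_matrix_to_natural(matrix(best$par, 1), spec)),
    par_layout(spec)$natural_names)
  list(params = row_to_params(u_nat, spec), u = best$par,
       logpost = -best$value, converged = TRUE)
}

# Central-difference Hessian with relative step h * max(1, |x_j|)
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  step <- h * pmax(1, abs(x))
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + step[i]
        xm <- x; xm[i] <- x[i] - step[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / step[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + step[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + step[i]; xpm[j] <- x[j] - step[j]
        xmp <- x; xmp[i] <- x[i] - step[i]; xmp[j] <- x[j] + step[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - step[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * step[i] * step[j])
      }
    }
  }
  H
}

#' Laplace approximation to a log marginal likelihood
#'
#' Generic Laplace evidence for a unimodal log posterior: with `u*` the mode
#' of the unnormalized log posterior `f` and `H` the negative Hessian of `f`
#' at `u*` (central finite differences), the approximation is
#' `f(u*) + (d/2) log(2 pi) - log|H| / 2`.  Exact when the posterior is
#' Gaussian.
#'
#' @param logpost Function of a numeric vector returning the unnormalized
#'   log posterior (log-likelihood + log prior, with any transform
#'   Jacobians).
#' @param mode Numeric vector, the posterior mode.
#' @param h Relative finite-difference step (default 1e-4).
#' @return Scalar log marginal likelihood estimate.
#' @export
laplace_evidence <- function(logpost, mode, h = 1e-4) {
  H <- -fd_hessian(logpost, mode, h)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("negative-log-posterior Hessian not positive definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 3), ")")
  d <- length(mode)
  logpost(mode) + d / 2 * log(2 * pi) - 0.5 * sum(log(ev))
}

#' Laplace log marginal likelihood of a CFA model
#'
#' Finds the MAP on the unconstrained scale and applies the Laplace
#' approximation there (the prior density carries the transform Jacobians,
#' so the result approximates the marginal likelihood of the model).
#'
#' @inheritParams map_estimate
#' @param h Relative finite-difference Hessian step.
#' @return Scalar log marginal likelihood.
#' @export
laplace_log_marginal <- function(moments, spec, priors = cfa_priors(),
                                 n_starts = 5, seed = NULL, h = 1e-4) {
  map <- map_estimate(moments, spec, priors, n_starts = n_starts, seed = seed)
  prior_list <- priors_as_list(priors)
  fn <- function(u) cpp_log_posterior(u, moments$S, moments$ybar, moments$N,
                                      spec$p, spec$m,
                                      as.integer(spec$factor_of), spec$is_ref,
                                      prior_list, 1)
  laplace_evidence(fn, map$u, h = h)
}

#' Bayes factor from two log marginal likelihoods
#'
#' @param logml_a,logml_b Log marginal likelihoods of models A and B.
#' @return Object of class `bayes_factor` with `logbf` (natural log),
#'   `log10bf`, and `bf` (`Inf` when it overflows; use the log scales).
#' @examples
#' bayes_factor(log(10), 0)  # BF = 10
#' @export
bayes_factor <- function(logml_a, logml_b) {
  logbf <- logml_a - logml_b
  structure(list(logbf = logbf, log10bf = logbf / log(10),
                 bf = exp(logbf)),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat("Bayes factor (A over B): ")
  cat(format_bf(x$log10bf), "  [log10 BF =",
      format(x$log10bf, digits = 4), "]\n")
  invisible(x)
}

# base-10 scientific string, safe for extreme magnitudes
format_bf <- function(log10bf) {
  e <- floor(log10bf)
  mant <- 10^(log10bf - e)
  sprintf("%.2f x 10^%d", mant, as.integer(e))
}

#' Compare a set of factorial structures by Laplace Bayes factors
#'
#' Computes the Laplace log marginal likelihood of each model on the same
#' data and the pairwise log10 Bayes factor matrix.
#'
#' @param moments A [sample_moments()] object.
#' @param specs Named list of [cfa_spec()] objects.
#' @param priors A [cfa_priors()] object.
#' @param n_starts Starts per MAP search.
#' @param seed Optional integer seed.
#' @return Object of class `bcfa_comparison` with `log_marginal` (named
#'   vector) and `log10bf` (matrix, row model over column model).
#' @export
compare_models <- function(moments, specs, priors = cfa_priors(),
                           n_starts = 5, seed = NULL) {
  stopifnot(is.list(specs), length(specs) >= 2, !is.null(names(specs)))
  if (!is.null(seed)) set.seed(seed)
  logml <- vapply(specs, function(sp)
    laplace_log_marginal(moments, sp, priors, n_starts = n_starts),
    numeric(1))
  lb <- outer(logml, logml, `-`) / log(10)
  dimnames(lb) <- list(names(specs), names(specs))
  structure(list(log_marginal = logml, log10bf = lb),
            class = "bcfa_comparison")
}

#' @export
print.bcfa_comparison <- function(x, ...) {
  cat("Laplace log marginal likelihoods:\n")
  print(round(x$log_marginal, 2))
  cat("\nlog10 Bayes factors (row over column):\n")
  print(round(x$log10bf, 2))
  best <- names(which.max(x$log_marginal))
  cat("\nbest-supported model:", best, "\n")
  invisible(x)
}
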