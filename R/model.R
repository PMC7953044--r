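#' Construct a CFA parameter point
#'
#' Bundles one point in parameter space for a given model structure: item
#' intercepts `nu`, loadings `lambda` (including the reference loadings fixed
#' at 1), residual variances `theta`, latent standard deviations `factor_sd`,
#' and the factor correlation matrix `factor_corr`.
#'
#' @param spec A [cfa_spec()].
#' @param nu Numeric vector of `p` intercepts.
#' @param lambda Numeric vector of `p` loadings (ignored entries for the
#'   independence model); values at reference items must equal 1.
#' @param theta Numeric vector of `p` residual variances (> 0).
#' @param factor_sd Numeric vector of `m` latent standard deviations (> 0).
#' @param factor_corr `m` by `m` correlation matrix (unit diagonal,
#'   symmetric, positive definite).
#' @return An object of class `cfa_parameters`.
#' @export
cfa_parameters <- function(spec, nu, lambda = NULL, theta,
                           factor_sd = NULL, factor_corr = NULL) {
  stopifnot(inherits(spec, "cfa_spec"))
  p <- spec$p; m <- spec$m
  nu <- as.numeric(nu); theta <- as.numeric(theta)
  if (length(nu) != p || length(theta) != p)
    stop("'nu' and 'theta' must have length ", p)
  if (any(theta <= 0)) stop("'theta' must be strictly positive")
  if (m > 0) {
    lambda <- as.numeric(lambda)
    if (length(lambda) != p) stop("'lambda' must have length ", p)
    if (any(abs(lambda[spec$is_ref] - 1) > 1e-12))
      stop("loadings at reference items must equal 1")
    factor_sd <- as.numeric(factor_sd)
    if (length(factor_sd) != m || any(factor_sd <= 0))
      stop("'factor_sd' must be ", m, " positive values")
    if (is.null(factor_corr)) factor_corr <- diag(m)
    factor_corr <- as.matrix(factor_corr)
    check_correlation_matrix(factor_corr, m, "factor_corr")
  } else {
    lambda <- numeric(p); factor_sd <- numeric(0); factor_corr <- diag(0)
  }
  if (m > 0) dimnames(factor_corr) <- list(spec$factor_names, spec$factor_names)
  structure(list(nu = stats::setNames(nu, spec$item_names),
                 lambda = stats::setNames(lambda, spec$item_names),
                 theta = stats::setNames(theta, spec$item_names),
                 factor_sd = stats::setNames(factor_sd, spec$factor_names),
                 factor_corr = factor_corr,
                 spec = spec),
            class = "cfa_parameters")
}

check_correlation_matrix <- function(R, m, name) {
  if (!all(dim(R) == c(m, m)) || any(abs(diag(R) - 1) > 1e-8) ||
      any(abs(R - t(R)) > 1e-8))
    stop("'", name, "' must be a symmetric ", m, "x", m,
         " matrix with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("'", name, "' is not positive definite (smallest eigenvalue ",
         format(min(ev), digits = 3), ")")
  invisible(TRUE)
}

#' @export
print.cfa_parameters <- function(x, digits = 3, ...) {
  cat("CFA parameters (", x$spec$m, " factor(s), ", x$spec$p, " items)\n",
      sep = "")
  tab <- cbind(nu = x$nu, lambda = x$lambda, theta = x$theta)
  print(round(tab, digits))
  if (x$spec$m > 0) {
    cat("factor SDs:\n"); print(round(x$factor_sd, digits))
    if (x$spec$m > 1) { cat("factor correlations:\n")
      print(round(x$factor_corr, digits)) }
  }
  invisible(x)
}

#' Model-implied moments
#'
#' The implied mean vector is the intercept vector (latent means fixed at 0)
#' and the implied covariance is `Lambda Phi Lambda' + diag(theta)` with
#' `Phi = diag(factor_sd) %*% factor_corr %*% diag(factor_sd)`.
#'
#' @param params A [cfa_parameters()] object.
#' @return List with components `mu` (length `p`) and `sigma` (`p` by `p`).
#' @export
implied_moments <- function(params) {
  stopifnot(inherits(params, "cfa_parameters"))
  spec <- params$spec
  p <- spec$p; m <- spec$m
  if (m > 0) {
    L <- matrix(0, p, m, dimnames = list(spec$item_names, spec$factor_names))
    L[cbind(seq_len(p), spec$factor_of)] <- params$lambda
    Phi <- diag(params$factor_sd, m) %*% params$factor_corr %*%
      diag(params$factor_sd, m)
    sigma <- L %*% Phi %*% t(L)
    diag(sigma) <- diag(sigma) + params$theta
  } else {
    sigma <- diag(params$theta, p)
  }
  dimnames(sigma) <- list(spec$item_names, spec$item_names)
  list(mu = params$nu, sigma = sigma)
}

#' Sample moments of a complete item-response matrix
#'
#' Column means and the maximum-likelihood covariance matrix (divisor `N`,
#' not `N - 1`), together with the number of unique sample moments
#' `p_star = p (p + 3) / 2`.  The divisor-`N` convention makes the
#' chi-square discrepancy equal `2 (L_sat - L_model)` exactly.
#'
#' @param x Numeric matrix or data frame, respondents in rows, items in
#'   columns, no missing values (see [complete_cases()]).
#' @return Object of class `sample_moments` with fields `ybar`, `S`, `N`,
#'   `p`, `p_star`.
#' @export
sample_moments <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (anyNA(x))
    stop("missing values present; apply complete_cases() first")
  N <- nrow(x); p <- ncol(x)
  if (N < 1) stop("no observations")
  if (N < p + 1)
    warning("fewer observations than items + 1; sample covariance is singular")
  ybar <- colMeans(x)
  xc <- sweep(x, 2, ybar)
  S <- crossprod(xc) / N
  if (any(diag(S) <= .Machine$double.eps * 100))
    warning("constant column(s) detected; sample covariance is singular")
  structure(list(ybar = ybar, S = S, N = N, p = p,
                 p_star = p * (p + 3) / 2),
            class = "sample_moments")
}

#' @export
print.sample_moments <- function(x, ...) {
  cat("Sample moments: N =", x$N, ", p =", x$p,
      ", unique moments p* =", x$p_star, "\n")
  invisible(x)
}

#' Marginal log-likelihood of a CFA parameter point
#'
#' The multivariate-normal log-likelihood with the latent variables
#' integrated out, evaluated from sufficient statistics:
#' `-(N/2) [ p log(2 pi) + log|Sigma| + tr(S Sigma^-1) +
#' (ybar - mu)' Sigma^-1 (ybar - mu) ]`.
#' Returns `-Inf` (not an error) when the implied covariance is not positive
#' definite, so rejection-based samplers and optimizers can use it directly.
#'
#' @param params A [cfa_parameters()] object.
#' @param sm A [sample_moments()] object.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(params, sm) {
  stopifnot(inherits(sm, "sample_moments"))
  im <- implied_moments(params)
  R <- tryCatch(chol(im$sigma), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  tr <- sum(diag(chol2inv(R) %*% sm$S))
  dv <- backsolve(R, sm$ybar - im$mu, transpose = TRUE)
  -0.5 * sm$N * (sm$p * log(2 * pi) + logdet + tr + sum(dv^2))
}

#' Completely standardized solution
#'
#' Rescales a parameter point so that both items and factors have unit
#' variance: `lambda*_j = lambda_j sd(factor) / sqrt(sigma_jj)` and
#' `theta*_j = theta_j / sigma_jj`, where `sigma_jj` is the model-implied
#' item variance; factor SDs become 1 and the factor correlations are
#' unchanged.  Per item `lambda*^2 + theta* = 1`.  Intercepts are left on
#' the raw response scale.  The operation is idempotent.
#'
#' @param params A [cfa_parameters()] object.
#' @return A [cfa_parameters()] object on the standardized scale.
#' @export
standardize <- function(params) {
  stopifnot(inherits(params, "cfa_parameters"))
  spec <- params$spec
  if (spec$m == 0) return(params)
  sigma_jj <- diag(implied_moments(params)$sigma)
  if (any(sigma_jj <= 0)) stop("zero implied item variance")
  fsd <- params$factor_sd[spec$factor_of]
  lam_std <- params$lambda * fsd / sqrt(sigma_jj)
  theta_std <- params$theta / sigma_jj
  out <- params
  out$lambda <- stats::setNames(lam_std, spec$item_names)
  out$theta <- stats::setNames(theta_std, spec$item_names)
  out$factor_sd <- stats::setNames(rep(1, spec$m), spec$factor_names)
  # reference-loading constraint no longer applies on this scale
  out$spec$is_ref <- rep(FALSE, spec$p)
  out$spec$reference_items <- character(0)
  class(out) <- c("cfa_parameters_std", "cfa_parameters")
  out
}
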