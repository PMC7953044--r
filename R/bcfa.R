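#' Fit a Bayesian CFA by MCMC on the marginal likelihood
#'
#' Samples the posterior of the model parameters under the [cfa_priors()]
#' prior set, using the multivariate-normal likelihood with the latent
#' variables integrated out (so only the sample moments of the data enter).
#' The sampler is an adaptive random-walk Metropolis-within-Gibbs on
#' unconstrained transforms (log standard deviations, atanh correlations);
#' one recorded iteration consists of `sweeps` full coordinate scans, with
#' proposal scales adapted during warmup and frozen afterwards.  Each chain
#' runs from its own seed derived from `seed`.
#'
#' @param data Numeric matrix or data frame of item responses with no
#'   missing values (see [complete_cases()]).  May be omitted when `moments`
#'   is supplied or when `sample_prior = TRUE`.
#' @param spec A [cfa_spec()] describing the factor structure.
#' @param priors A [cfa_priors()] object.
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_warmup,n_kept Warmup (discarded) and kept iterations per chain.
#' @param sweeps Full coordinate scans per recorded iteration.
#' @param seed Integer master seed.
#' @param sample_prior If `TRUE` the likelihood is switched off and the
#'   chains sample the prior (used for prior predictive checks and tests).
#' @param moments Optionally, precomputed [sample_moments()] instead of
#'   `data`.
#' @return An object of class `bcfa` with components `draws` (array
#'   `n_kept` x parameters x chains on the natural scale), `spec`, `priors`,
#'   `moments`, `convergence` (per-parameter PSRF/MCSE report), `converged`
#'   flag, and sampler metadata.
#' @examples
#' y <- generate_responses(mspss_parameters(), n = 300, seed = 1)
#' fit <- bcfa(y, mspss_spec("three"), n_chains = 2, n_warmup = 100,
#'             n_kept = 100, sweeps = 2, seed = 1)
#' @export
bcfa <- function(data = NULL, spec, priors = cfa_priors(), n_chains = 3,
                 n_warmup = 1000, n_kept = 1000, sweeps = 8, seed = 1,
                 sample_prior = FALSE, moments = NULL) {
  stopifnot(inherits(spec, "cfa_spec"), n_chains >= 1, n_kept >= 1)
  if (is.null(moments)) {
    if (!is.null(data)) {
      data <- as.matrix(data)
      if (!is.null(colnames(data)) &&
          !identical(colnames(data), spec$item_names)) {
        if (!all(spec$item_names %in% colnames(data)))
          stop("data columns do not match spec item names")
        data <- data[, spec$item_names, drop = FALSE]
      }
      moments <- sample_moments(data)
    } else if (sample_prior) {
      moments <- structure(list(ybar = numeric(spec$p), S = diag(spec$p),
                                N = spec$p + 1, p = spec$p,
                                p_star = spec$p * (spec$p + 3) / 2),
                           class = "sample_moments")
    } else {
      stop("either 'data' or 'moments' must be supplied")
    }
  }
  if (moments$p != spec$p) stop("moments and spec disagree on item count")
  if (!sample_prior && moments$N < spec$p + 1)
    stop("need at least p + 1 complete cases")

  lik_weight <- if (sample_prior) 0 else 1
  layout <- par_layout(spec)
  u0 <- if (sample_prior) prior_start(spec) else moment_start(moments, spec)
  prior_list <- priors_as_list(priors)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, n_chains)
  draws <- array(NA_real_, c(n_kept, layout$d, n_chains),
                 dimnames = list(NULL, layout$natural_names, NULL))
  accept <- matrix(NA_real_, layout$d, n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    u_start <- jitter_start(u0, spec, priors, moments, lik_weight)
    res <- cpp_mwg_sampler(moments$S, moments$ybar, moments$N, spec$p,
                           spec$m, as.integer(spec$factor_of),
                           spec$is_ref, prior_list, u_start,
                           as.integer(n_warmup), as.integer(n_kept),
                           as.integer(sweeps), lik_weight,
                           initial_steps(spec, sample_prior))
    draws[, , ch] <- u_matrix_to_natural(res$draws, spec)
    accept[, ch] <- res$accept
  }

  conv <- convergence_report(draws)
  converged <- all(conv$psrf < 1.1, na.rm = TRUE)
  fit <- structure(
    list(draws = draws, spec = spec, priors = priors, moments = moments,
         n_chains = n_chains, n_warmup = n_warmup, n_kept = n_kept,
         sweeps = sweeps, seed = seed, chain_seeds = chain_seeds,
         accept = accept, convergence = conv, converged = converged,
         sample_prior = sample_prior, call = match.call()),
    class = "bcfa")
  if (!converged && !sample_prior)
    warning("convergence not reached: max PSRF = ",
            format(max(conv$psrf, na.rm = TRUE), digits = 4),
            " (threshold 1.1); consider more iterations")
  fit
}

# ---- unconstrained / natural parameter layout -------------------------------

par_layout <- function(spec) {
  p <- spec$p; m <- spec$m
  nm_items <- spec$item_names
  nat <- paste0("nu[", nm_items, "]")
  if (m > 0)
    nat <- c(nat, paste0("lambda[", nm_items[!spec$is_ref], "]"))
  nat <- c(nat, paste0("theta[", nm_items, "]"))
  if (m > 0) nat <- c(nat, paste0("psi_sd[", spec$factor_names, "]"))
  if (m > 1) {
    pairs <- corr_pairs(spec)
    nat <- c(nat, paste0("corr[", pairs[, 1], ",", pairs[, 2], "]"))
  }
  list(d = length(nat), natural_names = nat)
}

# lower-triangle order (2,1),(3,1),(3,2) matching the C++ layout
corr_pairs <- function(spec) {
  m <- spec$m
  out <- NULL
  for (cc in seq_len(m)) for (rr in seq_len(m)) {
    if (rr > cc)
      out <- rbind(out, c(spec$factor_names[cc], spec$factor_names[rr]))
  }
  out
}

# columnwise transform of a kept matrix of unconstrained draws to the
# natural scale (theta = variances, psi_sd = SDs, corr in (-1,1))
u_matrix_to_natural <- function(u, spec) {
  p <- spec$p; m <- spec$m
  nfree <- if (m > 0) p - m else 0
  off <- p + nfree
  u[, (off + 1):(off + p)] <- exp(2 * u[, (off + 1):(off + p), drop = FALSE])
  off <- off + p
  if (m > 0)
    u[, (off + 1):(off + m)] <- exp(u[, (off + 1):(off + m), drop = FALSE])
  off <- off + m
  if (m > 1) {
    ncorr <- m * (m - 1) / 2
    u[, (off + 1):(off + ncorr)] <-
      tanh(u[, (off + 1):(off + ncorr), drop = FALSE])
  }
  u
}

# one natural-scale draw (named vector) -> cfa_parameters
row_to_params <- function(v, spec) {
  p <- spec$p; m <- spec$m
  nu <- v[seq_len(p)]
  off <- p
  lambda <- rep(1, p)
  if (m > 0) {
    nfree <- p - m
    lambda[!spec$is_ref] <- v[off + seq_len(nfree)]
    off <- off + nfree
  }
  theta <- v[off + seq_len(p)]; off <- off + p
  if (m > 0) {
    fsd <- v[off + seq_len(m)]; off <- off + m
    fc <- diag(m)
    if (m > 1) {
      fc[lower.tri(fc)] <- v[off + seq_len(m * (m - 1) / 2)]
      fc[upper.tri(fc)] <- t(fc)[upper.tri(fc)]
    }
  } else {
    fsd <- NULL; fc <- NULL; lambda <- NULL
  }
  cfa_parameters(spec, nu = nu, lambda = lambda, theta = theta,
                 factor_sd = fsd, factor_corr = fc)
}

# ---- starting values --------------------------------------------------------

moment_start <- function(sm, spec) {
  p <- spec$p; m <- spec$m
  dS <- pmax(diag(sm$S), 1e-4)
  u <- sm$ybar
  if (m > 0) u <- c(u, rep(1, p - m))
  u <- c(u, 0.5 * log(dS / 2))
  if (m > 0) {
    ref <- match(spec$reference_items, spec$item_names)
    u <- c(u, 0.5 * log(pmax(dS[ref] / 2, 1e-4)))
  }
  if (m > 1) u <- c(u, rep(atanh(0.3), m * (m - 1) / 2))
  unname(u)
}

prior_start <- function(spec) {
  numeric(par_layout(spec)$d)
}

jitter_start <- function(u0, spec, priors, sm, lik_weight, tries = 20) {
  prior_list <- priors_as_list(priors)
  scale <- 0.1
  for (i in seq_len(tries)) {
    u <- u0 + stats::rnorm(length(u0), 0, scale)
    lp <- cpp_log_posterior(u, sm$S, sm$ybar, sm$N, spec$p, spec$m,
                            as.integer(spec$factor_of), spec$is_ref,
                            prior_list, lik_weight)
    if (is.finite(lp)) return(u)
    scale <- scale / 2
  }
  u0
}

initial_steps <- function(spec, sample_prior) {
  p <- spec$p; m <- spec$m
  s <- rep(0.05, p)                       # nu
  if (m > 0) s <- c(s, rep(0.05, p - m))  # lambda
  s <- c(s, rep(0.05, p))                 # log resid sd
  if (m > 0) s <- c(s, rep(0.05, m))      # log factor sd
  if (m > 1) s <- c(s, rep(0.05, m * (m - 1) / 2))
  if (sample_prior) s[] <- 1
  s
}

# ---- pooled / standardized draws -------------------------------------------

#' Posterior draws as a pooled matrix
#'
#' Concatenates the chains of a fitted model into one matrix of natural-scale
#' draws (rows = `n_kept * n_chains`, chain-major order).
#' @param fit A [bcfa()] fit.
#' @return Numeric matrix with named parameter columns.
#' @export
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "bcfa"))
  d <- fit$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch]))
  colnames(out) <- dimnames(d)[[2]]
  out
}

# Completely standardized draws: for every draw, standardized loadings for
# all p items, standardized residual variances, intercepts (raw scale),
# factor correlations.  Returns an array iter x params x chains.
standardized_draws <- function(fit) {
  spec <- fit$spec
  p <- spec$p; m <- spec$m
  stopifnot(m > 0)
  nm <- c(paste0("lambda_std[", spec$item_names, "]"),
          paste0("nu[", spec$item_names, "]"),
          paste0("theta_std[", spec$item_names, "]"),
          if (m > 1) {
            pairs <- corr_pairs(spec)
            paste0("corr[", pairs[, 1], ",", pairs[, 2], "]")
          })
  n_chains <- dim(fit$draws)[3]
  out <- array(NA_real_, c(fit$n_kept, length(nm), n_chains),
               dimnames = list(NULL, nm, NULL))
  nfree <- p - m
  ncorr <- if (m > 1) m * (m - 1) / 2 else 0
  for (ch in seq_len(n_chains)) {
    x <- fit$draws[, , ch, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = fit$n_kept)
    nu <- x[, seq_len(p), drop = FALSE]
    lambda <- matrix(1, nrow(x), p)
    lambda[, !spec$is_ref] <- x[, p + seq_len(nfree), drop = FALSE]
    theta <- x[, p + nfree + seq_len(p), drop = FALSE]
    fsd <- x[, 2 * p + nfree + seq_len(m), drop = FALSE]
    fsd_item <- fsd[, spec$factor_of, drop = FALSE]
    sigma_jj <- lambda^2 * fsd_item^2 + theta
    lam_std <- lambda * fsd_item / sqrt(sigma_jj)
    theta_std <- theta / sigma_jj
    corr <- if (ncorr > 0)
      x[, 2 * p + nfree + m + seq_len(ncorr), drop = FALSE]
    out[, , ch] <- cbind(lam_std, nu, theta_std, corr)
  }
  out
}

# ---- methods ----------------------------------------------------------------

#' @export
print.bcfa <- function(x, ...) {
  cat("Bayesian CFA fit",
      if (x$sample_prior) "(prior sampling, likelihood off)", "\n")
  cat("  model: ", if (x$spec$m == 0) "independence" else
    paste0(x$spec$m, "-factor (",
           paste(x$spec$factor_names, collapse = ", "), ")"),
    ";  items: ", x$spec$p, ";  N = ", x$moments$N, "\n", sep = "")
  cat("  chains: ", x$n_chains, " x ", x$n_kept, " kept after ", x$n_warmup,
      " warmup (", x$sweeps, " sweeps/iteration)\n", sep = "")
  cat("  max PSRF: ", format(max(x$convergence$psrf, na.rm = TRUE),
                             digits = 4),
      if (x$converged) "  (converged)" else "  (NOT converged)", "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.bcfa <- function(object, standardized = FALSE, ...) {
  if (standardized) {
    sd3 <- standardized_draws(object)
    colMeans(pool_array(sd3))
  } else {
    colMeans(pooled_draws(object))
  }
}

pool_array <- function(a) {
  out <- do.call(rbind, lapply(seq_len(dim(a)[3]), function(ch) a[, , ch]))
  colnames(out) <- dimnames(a)[[2]]
  out
}

#' Posterior-mean parameter point
#'
#' The natural-scale posterior mean of every parameter, assembled into a
#' [cfa_parameters()] object (the plug-in point used for the effective
#' number of parameters).
#' @param fit A [bcfa()] fit.
#' @return A [cfa_parameters()] object.
#' @export
posterior_mean_parameters <- function(fit) {
  row_to_params(colMeans(pooled_draws(fit)), fit$spec)
}

#' @export
summary.bcfa <- function(object, level = 0.95, ...) {
  tab <- parameter_table(object, level = level)
  structure(list(table = tab, fit = object), class = "summary.bcfa")
}

#' @export
print.summary.bcfa <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nPosterior summary (completely standardized solution):\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.bcfa <- function(object, ...) {
  implied_moments(posterior_mean_parameters(object))
}

#' @export
residuals.bcfa <- function(object, ...) {
  im <- fitted(object)
  list(means = object$moments$ybar - im$mu,
       covariance = object$moments$S - im$sigma)
}

#' @export
logLik.bcfa <- function(object, ...) {
  ll <- marginal_loglik(posterior_mean_parameters(object), object$moments)
  structure(ll, df = n_free_parameters(object$spec), class = "logLik")
}

#' @export
simulate.bcfa <- function(object, nsim = 1, seed = NULL,
                          mode = c("continuous", "likert"), ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pool <- pooled_draws(object)
  idx <- sample.int(nrow(pool), nsim, replace = nsim > nrow(pool))
  N <- object$moments$N
  lapply(idx, function(i) {
    im <- implied_moments(row_to_params(pool[i, ], object$spec))
    y <- matrix(stats::rnorm(N * object$spec$p), N) %*% chol(im$sigma)
    y <- sweep(y, 2, im$mu, `+`)
    if (mode == "likert") y <- pmin(pmax(round(y), 1), 5)
    colnames(y) <- object$spec$item_names
    y
  })
}

#' @export
plot.bcfa <- function(x, pars = NULL, ...) {
  nm <- dimnames(x$draws)[[2]]
  if (is.null(pars)) pars <- utils::head(nm, 4)
  pars <- intersect(pars, nm)
  old <- graphics::par(mfrow = c(length(pars), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (pp in pars) {
    graphics::matplot(x$draws[, pp, ], type = "l", lty = 1,
                      ylab = pp, xlab = "iteration", ...)
  }
  invisible(x)
}

#' Export trace series to CSV
#'
#' Writes one row per (chain, iteration) with a column per parameter, so the
#' file has `n_chains * n_kept` data rows and round-trips through
#' [utils::read.csv()].
#' @param fit A [bcfa()] fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
trace_export <- function(fit, path) {
  stopifnot(inherits(fit, "bcfa"))
  nch <- dim(fit$draws)[3]
  df <- data.frame(chain = rep(seq_len(nch), each = fit$n_kept),
                   iteration = rep(seq_len(fit$n_kept), nch))
  df <- cbind(df, as.data.frame(pool_array(fit$draws)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
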