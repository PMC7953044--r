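#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Computes, per parameter, `sqrt( ((n-1)/n * W + B/n) / W )` across chains
#' (unsplit), where `W` is the mean within-chain variance and `B/n` the
#' variance of the chain means.  Values close to 1 and below 1.1 are taken
#' as convergence evidence; values slightly below 1 are sampling noise and
#' reported as-is.
#'
#' @param draws A 3-d array `iterations x parameters x chains` (as stored in
#'   a [bcfa()] fit), or a matrix `iterations x chains` for one parameter.
#' @return Named vector of PSRF values; `NaN` (with a warning) where the
#'   within-chain variance is zero.
#' @export
psrf <- function(draws) {
  if (is.matrix(draws)) draws <- array(draws, c(nrow(draws), 1, ncol(draws)))
  stopifnot(length(dim(draws)) == 3)
  n <- dim(draws)[1]; n_chains <- dim(draws)[3]
  if (n_chains < 2) stop("PSRF requires at least 2 chains")
  if (n < 10) stop("PSRF requires at least 10 iterations per chain")
  out <- vapply(seq_len(dim(draws)[2]), function(j) {
    x <- draws[, j, ]
    W <- mean(apply(x, 2, stats::var))
    if (W <= 0) return(NaN)
    B_over_n <- stats::var(colMeans(x))
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  names(out) <- dimnames(draws)[[2]]
  if (anyNA(out)) warning("zero within-chain variance for some parameter(s)")
  out
}

#' Monte Carlo standard error by batch means
#'
#' Splits the pooled kept draws (chains concatenated) into batches of size
#' `floor(sqrt(s))` and estimates the MCSE of the posterior mean as
#' `sqrt(var(batch means) / n_batches)`.
#'
#' @param draws A 3-d array `iterations x parameters x chains`, or a numeric
#'   vector/matrix of draws for one or more parameters.
#' @return Named vector of MCSE values.
#' @export
mcse_batch_means <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) {
    x <- pool_array(draws)
  } else if (is.matrix(draws)) {
    x <- draws
  } else {
    x <- matrix(as.numeric(draws), ncol = 1)
  }
  s <- nrow(x)
  if (s < 100) stop("batch-means MCSE requires at least 100 draws")
  b <- floor(sqrt(s))
  n_batches <- floor(s / b)
  idx <- rep(seq_len(n_batches), each = b)
  out <- vapply(seq_len(ncol(x)), function(j) {
    bm <- tapply(x[seq_along(idx), j], idx, mean)
    sqrt(stats::var(as.numeric(bm)) / n_batches)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

# Per-parameter convergence report: posterior mean/sd, PSRF, batch-means
# MCSE, and the two acceptance flags (PSRF < 1.1, MCSE < 5% of posterior sd).
convergence_report <- function(draws) {
  pooled <- pool_array(draws)
  post_mean <- colMeans(pooled)
  post_sd <- apply(pooled, 2, stats::sd)
  r <- if (dim(draws)[3] >= 2) suppressWarnings(psrf(draws))
       else rep(NA_real_, ncol(pooled))
  m <- if (nrow(pooled) >= 100) mcse_batch_means(draws)
       else rep(NA_real_, ncol(pooled))
  data.frame(parameter = colnames(pooled), mean = post_mean, sd = post_sd,
             psrf = unname(r), mcse = unname(m),
             psrf_ok = unname(r) < 1.1,
             mcse_ok = unname(m) < 0.05 * post_sd,
             row.names = NULL)
}
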