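#' Subscale total scores
#'
#' Per respondent, the sum of a factor's items; the score is missing when
#' any constituent item is missing.  Intended for Likert-mode (integer 1-5)
#' responses, so a four-item subscale scores in \[4, 20\].
#'
#' @param x Item-response matrix (missing values allowed).
#' @param spec A [cfa_spec()] with at least one factor.
#' @return Numeric matrix `n` by `m`, one column per factor.
#' @export
subscale_scores <- function(x, spec) {
  stopifnot(inherits(spec, "cfa_spec"), spec$m > 0)
  x <- as.matrix(x)
  v <- x[!is.na(x)]
  if (any(v != round(v)))
    stop("subscale totals require integer (likert) responses")
  out <- sapply(spec$factor_names, function(f) {
    items <- spec$factors[[f]]
    cols <- if (!is.null(colnames(x))) x[, items, drop = FALSE]
            else x[, match(items, spec$item_names), drop = FALSE]
    rowSums(cols)  # NA if any item missing
  })
  colnames(out) <- spec$factor_names
  out
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation on pairwise-complete observations.
#'
#' @param x,y Paired numeric vectors (missing allowed; pairwise exclusion is
#'   applied).
#' @return Scalar tau-b in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("tau is undefined when a variable is constant")
  stats::cor(x, y, method = "kendall")
}

#' Bayesian Kendall's tau with a uniform prior
#'
#' Posterior inference for the population Kendall correlation via the
#' asymptotic normal approximation to the standardized tau statistic
#' (`T* | tau ~ N(1.5 tau sqrt(n), 1)`), combined with a uniform prior on
#' \[-1, 1\].  The Bayes factor for a nonzero association is the
#' Savage-Dickey density ratio at `tau = 0`; the posterior is evaluated on a
#' fine grid, which keeps all quantities finite on the log scale even for
#' extreme evidence.  Pairwise exclusion of missing values is applied first.
#'
#' @param x,y Paired score vectors (>= 10 complete pairs required).
#' @param level Credible level for the central interval (default 0.90).
#' @param grid_n Number of grid points over (-1, 1).
#' @return Object of class `kendall_bf` with fields `tau` (observed tau-b),
#'   `n` (complete pairs), `bf10`, `log10_bf10`, `post_mean`, and `ci`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- x + rnorm(200)
#' kendall_bayes(x, y)
#' @export
kendall_bayes <- function(x, y, level = 0.90, grid_n = 4001) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete pairs")
  tau <- kendall_tau(x, y)
  # standardized statistic; under H0 it is asymptotically standard normal
  t_star <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  grid <- seq(-1 + 1e-9, 1 - 1e-9, length.out = grid_n)
  logl <- stats::dnorm(t_star, mean = 1.5 * grid * sqrt(n), sd = 1,
                       log = TRUE)
  h <- grid[2] - grid[1]
  log_int <- log_sum_exp(logl) + log(h)     # log integral of likelihood
  log_post <- logl - log_int                # log posterior density on grid
  # Savage-Dickey: prior density at 0 is 1/2
  logl0 <- stats::dnorm(t_star, 0, 1, log = TRUE)
  log_bf10 <- log(0.5) - (logl0 - log_int)
  w <- exp(log_post - max(log_post)); w <- w / sum(w)
  post_mean <- sum(w * grid)
  cdf <- cumsum(w)
  a <- (1 - level) / 2
  ci <- c(grid[which.max(cdf >= a)], grid[which.max(cdf >= 1 - a)])
  structure(list(tau = tau, n = n, bf10 = exp(log_bf10),
                 log10_bf10 = log_bf10 / log(10),
                 post_mean = post_mean, ci = ci, level = level),
            class = "kendall_bf")
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' @export
print.kendall_bf <- function(x, digits = 3, ...) {
  cat(sprintf("Kendall's tau-b = %.*f  (n = %d)\n", digits, x$tau, x$n))
  cat(sprintf("  BF10 = %s   posterior mean = %.*f   %.0f%% CrI (%.*f, %.*f)\n",
              format_bf(x$log10_bf10), digits, x$post_mean, 100 * x$level,
              digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' Criterion validity report
#'
#' Bayesian Kendall correlations between every subscale total score and each
#' external criterion score, with pairwise exclusion of missing values.
#'
#' @param scores Matrix of subscale total scores (see [subscale_scores()]).
#' @param criteria Named list (or data frame) of external criterion score
#'   vectors aligned with the rows of `scores`.
#' @param level Credible level (default 0.90).
#' @return Data frame with columns subscale, criterion, n, tau, bf10,
#'   log10_bf10, ci_lo, ci_hi.
#' @export
validity_report <- function(scores, criteria, level = 0.90) {
  scores <- as.matrix(scores)
  criteria <- as.list(as.data.frame(criteria))
  rows <- list()
  for (sub in colnames(scores)) {
    for (cr in names(criteria)) {
      kb <- kendall_bayes(scores[, sub], criteria[[cr]], level = level)
      rows[[length(rows) + 1]] <-
        data.frame(subscale = sub, criterion = cr, n = kb$n, tau = kb$tau,
                   bf10 = kb$bf10, log10_bf10 = kb$log10_bf10,
                   ci_lo = kb$ci[1], ci_hi = kb$ci[2], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
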