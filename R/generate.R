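#' Generating parameters for synthetic MSPSS responses
#'
#' Returns the default truth set driving the synthetic-data generator:
#' completely standardized loadings and residual variances, raw-scale item
#' intercepts, and factor correlations for the three-factor (Significant
#' Other, Family, Friends) structure, taken from the posterior means
#' reported by a published validation of the 12-item MSPSS in a large
#' Australian adult sample (n = 3868 complete cases).  Item standard
#' deviations default to 1 (raw item SDs were not reported) and per-item
#' missingness rates are linearly spaced over the reported 0.02\%-0.18\%
#' range.
#'
#' For each item the standardized decomposition satisfies
#' `loading^2 + residual_variance = 1` (up to rounding of the published
#' values).
#'
#' @param item_sds Numeric vector of 12 raw-scale item standard deviations
#'   used to scale the standardized latent structure; default all 1.
#' @param missing_rates Numeric vector of 12 per-item MCAR missingness
#'   proportions; default `seq(0.0002, 0.0018, length.out = 12)`.
#' @return Object of class `generating_parameters` with fields `loadings`,
#'   `intercepts`, `residual_variances`, `factor_correlations`, `item_sds`,
#'   `missing_rates`, and `spec` (the three-factor [cfa_spec()]).
#' @examples
#' gp <- mspss_parameters()
#' gp$loadings[1]                      # 0.898
#' gp$factor_correlations["SO", "FA"]  # 0.636
#' @export
mspss_parameters <- function(item_sds = rep(1, 12),
                             missing_rates = seq(2e-04, 18e-04,
                                                 length.out = 12)) {
  stopifnot(length(item_sds) == 12, all(item_sds > 0),
            length(missing_rates) == 12,
            all(missing_rates >= 0), all(missing_rates < 1))
  spec <- mspss_spec("three")
  loadings <- c(0.898, 0.936, 0.908, 0.873,   # SO
                0.866, 0.924, 0.821, 0.829,   # FA
                0.862, 0.884, 0.881, 0.841)   # FR
  intercepts <- c(4.048, 4.272, 3.979, 4.126,
                  4.291, 4.037, 3.883, 4.072,
                  4.546, 4.430, 4.538, 4.249)
  residual_variances <- c(0.194, 0.124, 0.176, 0.238,
                          0.250, 0.146, 0.326, 0.314,
                          0.257, 0.219, 0.224, 0.292)
  fc <- diag(3)
  dimnames(fc) <- list(spec$factor_names, spec$factor_names)
  fc["SO", "FA"] <- fc["FA", "SO"] <- 0.636
  fc["SO", "FR"] <- fc["FR", "SO"] <- 0.505
  fc["FA", "FR"] <- fc["FR", "FA"] <- 0.537
  nm <- spec$item_names
  structure(list(loadings = stats::setNames(loadings, nm),
                 intercepts = stats::setNames(intercepts, nm),
                 residual_variances = stats::setNames(residual_variances, nm),
                 factor_correlations = fc,
                 item_sds = stats::setNames(item_sds, nm),
                 missing_rates = stats::setNames(missing_rates, nm),
                 spec = spec),
            class = "generating_parameters")
}

#' @export
print.generating_parameters <- function(x, ...) {
  cat("Generating parameters:", x$spec$p, "items,", x$spec$m, "factors\n")
  print(round(cbind(loading = x$loadings, intercept = x$intercepts,
                    resid_var = x$residual_variances,
                    item_sd = x$item_sds,
                    miss_rate = x$missing_rates), 4))
  cat("factor correlations:\n")
  print(x$factor_correlations)
  invisible(x)
}

#' Population moments implied by generating parameters
#'
#' Mean vector and covariance matrix of the continuous-mode generator:
#' `mu = intercepts`, `Sigma = D (Lambda Phi Lambda' + Theta) D` with
#' `D = diag(item_sds)`.
#' @param gp A [mspss_parameters()]-style object.
#' @return List with `mu` and `sigma`.
#' @export
population_moments <- function(gp) {
  stopifnot(inherits(gp, "generating_parameters"))
  spec <- gp$spec
  p <- spec$p
  L <- matrix(0, p, spec$m)
  L[cbind(seq_len(p), spec$factor_of)] <- gp$loadings
  sigma <- L %*% gp$factor_correlations %*% t(L)
  diag(sigma) <- diag(sigma) + gp$residual_variances
  D <- diag(gp$item_sds, p)
  sigma <- D %*% sigma %*% D
  dimnames(sigma) <- list(spec$item_names, spec$item_names)
  list(mu = gp$intercepts, sigma = sigma)
}

#' Generate synthetic item responses
#'
#' Draws latent factor scores from a multivariate normal with the generating
#' factor correlation matrix, adds independent normal residuals with the
#' generating residual variances, and maps to the response scale as
#' `y = intercepts + diag(item_sds) (Lambda eta + eps)`.  In `"likert"` mode
#' each value is rounded to the nearest integer and clipped to \[1, 5\];
#' `"continuous"` mode returns the raw values (and is the mode under which
#' the fitted mean-structure model is correctly specified).
#'
#' @param gp Generating parameters, see [mspss_parameters()].
#' @param n Number of respondents (>= 1).
#' @param mode `"continuous"` or `"likert"`.
#' @param seed Optional integer seed; identical inputs give identical output.
#' @return Numeric matrix `n` by `p` with item names as column names.
#' @examples
#' y <- generate_responses(mspss_parameters(), n = 100, seed = 1)
#' @export
generate_responses <- function(gp, n, mode = c("continuous", "likert"),
                               seed = NULL) {
  stopifnot(inherits(gp, "generating_parameters"), n >= 1)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  spec <- gp$spec
  p <- spec$p; m <- spec$m
  R <- tryCatch(chol(gp$factor_correlations), error = function(e)
    stop("factor_correlations is not positive definite"))
  eta <- matrix(stats::rnorm(n * m), n, m) %*% R
  L <- matrix(0, p, m)
  L[cbind(seq_len(p), spec$factor_of)] <- gp$loadings
  eps <- matrix(stats::rnorm(n * p), n, p) %*%
    diag(sqrt(gp$residual_variances), p)
  y <- eta %*% t(L) + eps
  y <- sweep(y, 2, gp$item_sds, `*`)
  y <- sweep(y, 2, gp$intercepts, `+`)
  if (mode == "likert") y <- pmin(pmax(round(y), 1), 5)
  colnames(y) <- spec$item_names
  y
}

#' Inject missing-completely-at-random values
#'
#' Each cell of item `j` is independently set to `NA` with probability
#' `rates[j]`.
#'
#' @param x Item-response matrix.
#' @param rates Per-item missingness proportions in \[0, 1).
#' @param seed Optional integer seed.
#' @return The matrix with `NA`s injected.
#' @export
inject_missingness <- function(x, rates, seed = NULL) {
  x <- as.matrix(x)
  if (length(rates) == 1) rates <- rep(rates, ncol(x))
  stopifnot(length(rates) == ncol(x))
  if (any(rates < 0) || any(rates >= 1))
    stop("'rates' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(x))) {
    if (rates[j] > 0)
      x[stats::runif(nrow(x)) < rates[j], j] <- NA
  }
  x
}

#' Retain complete cases
#'
#' Drops every row with at least one missing entry, preserving row order.
#' Errors when no complete rows remain.
#'
#' @param x Item-response matrix (or data frame).
#' @return Matrix of the complete rows.
#' @export
complete_cases <- function(x) {
  x <- as.matrix(x)
  keep <- stats::complete.cases(x)
  if (!any(keep)) stop("no complete cases remain")
  x[keep, , drop = FALSE]
}

#' Read and write item-response CSV files
#'
#' The on-disk format is a header row of item names and one respondent per
#' row; missing values are written as empty fields and read from empty
#' fields or `NA`.
#'
#' @param path File path.
#' @param mode `"likert"` (values restricted to 1..5, the default) or
#'   `"continuous"`.
#' @return `read_responses()` returns a numeric matrix; `write_responses()`
#'   returns `path` invisibly.
#' @export
read_responses <- function(path, mode = c("likert", "continuous")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("no respondent rows in ", path)
  x <- as.matrix(df)
  if (!is.numeric(x)) stop("non-numeric entries in ", path)
  if (mode == "likert") {
    v <- x[!is.na(x)]
    if (any(v != round(v)) || any(v < 1) || any(v > 5))
      stop("likert responses must be integers in 1..5")
  }
  x
}

#' @rdname read_responses
#' @param x Item-response matrix.
#' @export
write_responses <- function(x, path) {
  utils::write.csv(as.data.frame(as.matrix(x)), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
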