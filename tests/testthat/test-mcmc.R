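test_that("log prior matches the stated independent densities", {
  spec <- mspss_spec("three")
  priors <- cfa_priors()
  base <- random_params(spec)
  # residual SD 2 vs 1: gamma(1, rate 0.5) log-density difference = -0.5
  p1 <- base; p1$theta[1] <- 1
  p2 <- base; p2$theta[1] <- 4  # sd = 2
  expect_equal(log_prior(p2, priors) - log_prior(p1, priors),
               dgamma(2, 1, rate = 0.5, log = TRUE) -
                 dgamma(1, 1, rate = 0.5, log = TRUE))
  expect_equal(dgamma(2, 1, rate = 0.5, log = TRUE), log(0.5) - 1)
  # a zero loading contributes the N(0, 100) normalizing constant
  p3 <- base; p3$lambda[2] <- 0
  p4 <- base; p4$lambda[2] <- 10
  expect_equal(log_prior(p3, priors) - log_prior(p4, priors),
               -0.5 * 0 + 0.5 * 100 / 100)
  # outside the correlation support
  p5 <- base
  p5$factor_corr[1, 2] <- p5$factor_corr[2, 1] <- 1.5
  expect_identical(log_prior(p5, priors), -Inf)
  p6 <- base
  p6$factor_corr[1, 2] <- p6$factor_corr[2, 1] <- 0.99
  p6$factor_corr[1, 3] <- p6$factor_corr[3, 1] <- -0.99
  expect_identical(log_prior(p6, priors), -Inf)
})

test_that("R and C++ log posteriors agree on random points", {
  spec <- mspss_spec("three")
  priors <- cfa_priors()
  y <- fixture_data_small()
  sm <- sample_moments(y)
  pl <- bayescfa:::priors_as_list(priors)
  set.seed(3)
  for (i in 1:10) {
    par <- random_params(spec)
    # pack onto the unconstrained scale
    u <- c(par$nu, par$lambda[!spec$is_ref], 0.5 * log(par$theta),
           log(par$factor_sd), atanh(par$factor_corr[lower.tri(diag(3))]))
    cpp <- bayescfa:::cpp_log_posterior(u, sm$S, sm$ybar, sm$N, spec$p,
                                        spec$m, as.integer(spec$factor_of),
                                        spec$is_ref, pl, 1)
    # the unconstrained density carries the transform Jacobians:
    # d(sd)/d(log sd) = sd and d(tanh z)/dz = 1 - rho^2
    r_side <- marginal_loglik(par, sm) + log_prior(par, priors) +
      sum(0.5 * log(par$theta)) +
      sum(log(par$factor_sd)) +
      sum(log(1 - par$factor_corr[lower.tri(diag(3))]^2))
    expect_equal(cpp, r_side, tolerance = 1e-8)
  }
})

test_that("PSRF separates mixed from unmixed chains", {
  set.seed(1)
  good <- array(rnorm(10000 * 2), c(10000, 1, 2))
  expect_true(abs(psrf(good) - 1) < 0.01)
  bad <- array(c(rnorm(500), rnorm(500, 10)), c(500, 1, 2))
  expect_gt(psrf(bad), 1.1)
  expect_error(psrf(array(rnorm(100), c(100, 1, 1))), "2 chains")
  expect_warning(r0 <- psrf(array(1, c(100, 1, 2))), "zero")
  expect_true(is.nan(r0))
})

test_that("batch-means MCSE is calibrated for iid draws and zero for constants", {
  set.seed(2)
  x <- rnorm(10000)
  expect_equal(unname(mcse_batch_means(x)), 0.01, tolerance = 0.3)
  expect_equal(unname(mcse_batch_means(rep(2, 400))), 0)
  expect_error(mcse_batch_means(rnorm(50)), "100")
})

test_that("prior-only sampling recovers the prior moments", {
  pf <- bcfa(spec = mspss_spec("three"), sample_prior = TRUE, n_chains = 2,
             n_warmup = 500, n_kept = 2000, sweeps = 3, seed = 5)
  pool <- pooled_draws(pf)
  expect_equal(sd(pool[, "nu[q1]"]), 32, tolerance = 0.1)
  expect_equal(sd(pool[, "lambda[q2]"]), 10, tolerance = 0.1)
  expect_equal(mean(sqrt(pool[, "theta[q1]"])), 2, tolerance = 0.1)
  # PD truncation makes each correlation Beta(1.5, 1.5)-shaped on [-1, 1]:
  # mean 0 and standard deviation 1/2, not exactly uniform
  rho <- pool[, "corr[SO,FA]"]
  expect_lt(abs(mean(rho)), 0.05)
  expect_true(sd(rho) > 0.4 && sd(rho) < 0.6)
})

test_that("sampling is reproducible under a seed", {
  y <- fixture_data_small()
  f1 <- suppressWarnings(bcfa(y, mspss_spec("three"), n_chains = 2,
                              n_warmup = 50, n_kept = 50, sweeps = 2,
                              seed = 77))
  f2 <- suppressWarnings(bcfa(y, mspss_spec("three"), n_chains = 2,
                              n_warmup = 50, n_kept = 50, sweeps = 2,
                              seed = 77))
  expect_identical(f1$draws, f2$draws)
})

test_that("the moderate fixture fit converges and recovers the truth", {
  fit <- fixture_fit_three_small()
  expect_true(fit$converged)
  expect_true(all(fit$convergence$psrf < 1.1))
  co <- coef(fit, standardized = TRUE)
  gp <- mspss_parameters()
  # n = 1200: generating values recovered within sampling error
  expect_lt(max(abs(co[paste0("lambda_std[q", 1:12, "]")] - gp$loadings)),
            0.05)
  expect_lt(abs(co["corr[SO,FA]"] - 0.636), 0.07)
})

test_that("trace export writes one row per chain-iteration and round-trips", {
  fit <- fixture_fit_three_small()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  trace_export(fit, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), fit$n_chains * fit$n_kept)
  expect_equal(df[["lambda[q2]"]],
               as.numeric(fit$draws[, "lambda[q2]", ][, 1:2]))
})
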