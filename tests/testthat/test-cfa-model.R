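test_that("sample moments use the divisor-N convention", {
  x <- matrix(c(0, 2, 0, 2), 2, 2)
  sm <- suppressWarnings(sample_moments(x))  # N < p + 1 flags singularity
  expect_equal(unname(sm$ybar), c(1, 1))
  expect_equal(unname(sm$S), matrix(1, 2, 2))
  expect_equal(suppressWarnings(sample_moments(matrix(rnorm(60), 5, 12)))$p_star,
               90)
  expect_error(sample_moments(matrix(c(1, NA), 2, 1)), "complete_cases")
  expect_warning(sample_moments(cbind(rnorm(30), rep(1, 30))), "constant")
})

test_that("implied moments follow Lambda Phi Lambda' + Theta", {
  spec <- cfa_spec(list(F = c("a", "b")), item_names = c("a", "b"))
  par <- cfa_parameters(spec, nu = c(0, 0), lambda = c(1, 1),
                        theta = c(1, 1), factor_sd = 1)
  expect_equal(unname(implied_moments(par)$sigma),
               matrix(c(2, 1, 1, 2), 2))
  # zero-loading limit: diagonal implied covariance
  spec0 <- cfa_spec(list(), item_names = c("a", "b"))
  par0 <- cfa_parameters(spec0, nu = c(1, 2), theta = c(3, 4))
  expect_equal(unname(implied_moments(par0)$sigma), diag(c(3, 4)))
  # generator and model agree on the population covariance: express the
  # standardized solution in ULI form (reference loading 1, factor SD =
  # the reference item's standardized loading)
  gp <- mspss_parameters()
  spec3 <- gp$spec
  ref_load <- gp$loadings[spec3$is_ref][spec3$factor_of]
  par3 <- cfa_parameters(spec3, nu = gp$intercepts,
                         lambda = gp$loadings / ref_load,
                         theta = gp$residual_variances,
                         factor_sd = gp$loadings[spec3$is_ref],
                         factor_corr = gp$factor_correlations)
  expect_equal(implied_moments(par3)$sigma,
               population_moments(gp)$sigma, tolerance = 1e-12)
  expect_equal(implied_moments(par3)$sigma["q1", "q2"], 0.898 * 0.936)
})

test_that("marginal log-likelihood matches the closed univariate forms", {
  # saturated univariate: -(N/2)(log 2pi + log s2 + 1)
  set.seed(1)
  x <- matrix(rnorm(40, 2, 1.5))
  colnames(x) <- "a"
  sm <- sample_moments(x)
  spec <- cfa_spec(list(), item_names = "a")
  sat <- cfa_parameters(spec, nu = sm$ybar, theta = diag(sm$S))
  expect_equal(marginal_loglik(sat, sm),
               -(40 / 2) * (log(2 * pi) + log(sm$S[1, 1]) + 1))
  # hand value: N = 100, s2 = 1, means equal, sigma2 = 2
  sm2 <- structure(list(ybar = 0, S = matrix(1), N = 100, p = 1, p_star = 2),
                   class = "sample_moments")
  m2 <- cfa_parameters(spec, nu = 0, theta = 2)
  msat <- cfa_parameters(spec, nu = 0, theta = 1)
  expect_equal(2 * (marginal_loglik(msat, sm2) - marginal_loglik(m2, sm2)),
               100 * (log(2) - 0.5), tolerance = 1e-10)
  expect_equal(chisq_discrepancy(sm2, implied_moments(m2)),
               19.31, tolerance = 0.005)
})

test_that("chi-square discrepancy equals twice the log-likelihood gap", {
  set.seed(42)
  spec <- mspss_spec("three")
  y <- generate_responses(mspss_parameters(), 300, seed = 8)
  sm <- sample_moments(y)
  for (i in 1:10) {
    par <- random_params(spec)
    l_model <- marginal_loglik(par, sm)
    # saturated log-likelihood from the full sample covariance
    l_sat <- -0.5 * sm$N * (sm$p * log(2 * pi) +
                              determinant(sm$S)$modulus + sm$p)
    expect_equal(chisq_discrepancy(sm, implied_moments(par)),
                 2 * (as.numeric(l_sat) - l_model), tolerance = 1e-8)
  }
  # saturated model has zero discrepancy
  expect_equal(chisq_discrepancy(sm, list(mu = sm$ybar, sigma = sm$S)), 0,
               tolerance = 1e-6)
})

test_that("non-positive-definite implied covariance gives -Inf, not an error", {
  spec <- cfa_spec(list(F = c("a", "b")), item_names = c("a", "b"))
  par <- cfa_parameters(spec, nu = c(0, 0), lambda = c(1, 1),
                        theta = c(1, 1), factor_sd = 1)
  par$theta <- c(-1, -1)  # invalid point reached by a sampler proposal
  sm <- sample_moments(matrix(rnorm(20), 10, 2,
                              dimnames = list(NULL, c("a", "b"))))
  expect_identical(marginal_loglik(par, sm), -Inf)
})

test_that("standardization is idempotent and normalizes each item", {
  spec <- cfa_spec(list(F = c("a", "b")), item_names = c("a", "b"))
  par <- cfa_parameters(spec, nu = c(0, 0), lambda = c(1, 2),
                        theta = c(0.5, 1), factor_sd = 1)
  std <- standardize(par)
  expect_equal(unname(std$lambda[2]), 2 / sqrt(5))
  expect_equal(unname(std$theta[2]), 0.2)
  expect_true(all(abs(std$lambda^2 + std$theta - 1) < 1e-10))
  std2 <- standardize(std)
  expect_equal(std2$lambda, std$lambda, tolerance = 1e-12)
  expect_equal(std2$theta, std$theta, tolerance = 1e-12)
  # implied correlation matrix invariant under standardization
  for (i in 1:5) {
    pr <- random_params()
    expect_equal(cov2cor(implied_moments(standardize(pr))$sigma),
                 cov2cor(implied_moments(pr)$sigma), tolerance = 1e-10)
  }
})
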