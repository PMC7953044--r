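test_that("Laplace evidence is exact for the conjugate Gaussian toy", {
  # normal mean with known variance and conjugate normal prior: the
  # posterior is Gaussian, so the Laplace approximation equals the
  # closed-form log marginal likelihood
  set.seed(9)
  n <- 25; s2 <- 4; m0 <- 0; t2 <- 9
  x <- rnorm(n, 1.3, sqrt(s2))
  logpost <- function(u) {
    sum(dnorm(x, u, sqrt(s2), log = TRUE)) + dnorm(u, m0, sqrt(t2), log = TRUE)
  }
  post_var <- 1 / (n / s2 + 1 / t2)
  mode <- post_var * (sum(x) / s2 + m0 / t2)
  Sg <- s2 * diag(n) + t2
  exact <- -0.5 * (n * log(2 * pi) +
                     as.numeric(determinant(Sg)$modulus) +
                     drop(t(x - m0) %*% solve(Sg, x - m0)))
  expect_equal(laplace_evidence(logpost, mode), exact, tolerance = 1e-6)
})

test_that("bayes_factor is antisymmetric and transitive", {
  expect_equal(bayes_factor(1, 1)$bf, 1)
  expect_equal(bayes_factor(log(10), 0)$bf, 10)
  expect_equal(bayes_factor(2, 5)$logbf, -bayes_factor(5, 2)$logbf)
  expect_equal(bayes_factor(3, 1)$logbf,
               bayes_factor(3, 2)$logbf + bayes_factor(2, 1)$logbf)
  expect_match(bayescfa:::format_bf(3409.774), "x 10\\^3409")
})

test_that("MAP recovers the generating solution and beats the posterior mean in fit", {
  y <- fixture_data_small()
  sm <- sample_moments(y)
  map <- map_estimate(sm, mspss_spec("three"), seed = 2)
  std <- standardize(map$params)
  gp <- mspss_parameters()
  expect_lt(max(abs(std$lambda - gp$loadings)), 0.05)
  # discrepancy at the mode is no larger than the posterior-mean discrepancy
  fit <- fixture_fit_three_small()
  d_map <- chisq_discrepancy(sm, implied_moments(map$params))
  pp <- posterior_predictive(fit, seed = 4, thin = 10)
  expect_lte(d_map, mean(pp$d_obs))
})

test_that("Laplace marginal likelihoods prefer the generating structure", {
  y <- fixture_data_small()
  sm <- sample_moments(y)
  cmp <- compare_models(sm, list(one = mspss_spec("one"),
                                 three = mspss_spec("three")),
                        seed = 6)
  # three-factor data: decisive support for the three-factor model
  expect_gt(cmp$log10bf["three", "one"], 2)
  expect_equal(cmp$log10bf["three", "one"], -cmp$log10bf["one", "three"])
  # mode-stability: independent restarts agree closely
  m_a <- laplace_log_marginal(sm, mspss_spec("three"), seed = 1)
  m_b <- laplace_log_marginal(sm, mspss_spec("three"), seed = 99)
  expect_lt(abs(m_a - m_b), 0.1)
})

test_that("on one-factor data the Bayes factor usually favors one factor", {
  gp <- mspss_parameters()
  # collapse the generator to (essentially) a single factor
  gp$factor_correlations[] <- 0.999
  diag(gp$factor_correlations) <- 1
  wins <- 0
  for (r in 1:10) {
    y <- generate_responses(gp, 1000, seed = 200 + r)
    sm <- sample_moments(y)
    m1 <- laplace_log_marginal(sm, mspss_spec("one"), n_starts = 2,
                               seed = r)
    m3 <- laplace_log_marginal(sm, mspss_spec("three"), n_starts = 2,
                               seed = r)
    if (m1 > m3) wins <- wins + 1
  }
  expect_gte(wins, 6)
})
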