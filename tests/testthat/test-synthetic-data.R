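test_that("default generating parameters carry the published three-factor solution", {
  gp <- mspss_parameters()
  expect_equal(unname(gp$loadings[1]), 0.898)
  expect_equal(gp$factor_correlations["SO", "FA"], 0.636)
  expect_equal(gp$factor_correlations["SO", "FR"], 0.505)
  expect_equal(unname(gp$intercepts[9]), 4.546)
  # standardized decomposition: loading^2 + residual variance = 1 per item
  expect_true(all(abs(gp$loadings^2 + gp$residual_variances - 1) < 0.02))
  ev <- eigen(gp$factor_correlations, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(all(gp$missing_rates >= 2e-4 & gp$missing_rates <= 18e-4))
})

test_that("continuous-mode sample moments converge to the population moments", {
  gp <- mspss_parameters()
  y <- generate_responses(gp, 2e5, mode = "continuous", seed = 1)
  # correlation of two congeneric indicators = product of their loadings
  expect_equal(cor(y[, 1], y[, 2]), 0.898 * 0.936, tolerance = 0.01)
  pm <- population_moments(gp)
  S <- crossprod(sweep(y, 2, colMeans(y))) / nrow(y)
  expect_lt(max(abs(S - pm$sigma)), 0.01)
  expect_lt(max(abs(colMeans(y) - pm$mu)), 0.01)
})

test_that("zero loadings produce independent items", {
  gp <- mspss_parameters()
  gp$loadings[] <- 0
  gp$residual_variances[] <- 1
  y <- generate_responses(gp, 20000, seed = 2)
  off <- abs(cor(y)[upper.tri(diag(12))])
  expect_lt(max(off), 3 / sqrt(20000) * 1.5)
})

test_that("likert mode clips to 1..5 and keeps means near the intercepts", {
  gp <- mspss_parameters()
  y <- generate_responses(gp, 20000, mode = "likert", seed = 3)
  expect_true(all(y %in% 1:5))
  # ceiling clipping shrinks every mean toward the scale midpoint; the
  # attenuation reaches ~0.2 for the items with intercepts above 4.4
  dev <- colMeans(y) - gp$intercepts
  expect_true(all(dev < 0))
  expect_true(all(abs(dev) < 0.25))
})

test_that("generation is deterministic under a seed", {
  gp <- mspss_parameters()
  y1 <- generate_responses(gp, 500, mode = "likert", seed = 9)
  y2 <- generate_responses(gp, 500, mode = "likert", seed = 9)
  expect_identical(y1, y2)
  m1 <- inject_missingness(y1, gp$missing_rates, seed = 4)
  m2 <- inject_missingness(y2, gp$missing_rates, seed = 4)
  expect_identical(m1, m2)
})

test_that("a non-positive-definite correlation matrix is rejected by name", {
  gp <- mspss_parameters()
  gp$factor_correlations[1, 2] <- gp$factor_correlations[2, 1] <- 0.999
  gp$factor_correlations[1, 3] <- gp$factor_correlations[3, 1] <- -0.999
  expect_error(generate_responses(gp, 10, seed = 1),
               "factor_correlations")
})

test_that("MCAR injection hits the requested per-item rates", {
  y <- matrix(1, 1e5, 12, dimnames = list(NULL, paste0("q", 1:12)))
  expect_identical(inject_missingness(y, rep(0, 12), seed = 1), y)
  expect_error(inject_missingness(y, rep(1, 12)), "rates")
  ym <- inject_missingness(y, rep(0.001, 12), seed = 5)
  frac <- colMeans(is.na(ym))
  expect_true(all(abs(frac - 0.001) < 5e-4))
  # at the survey's scale the expected missing cells per item are single-digit
  expected <- 3899 * mspss_parameters()$missing_rates
  expect_true(all(expected >= 0.5 & expected <= 8))
})

test_that("complete-case filtering keeps order and errors when empty", {
  x <- matrix(1:9, 3, 3)
  x2 <- x; x2[2, 2] <- NA
  expect_equal(complete_cases(x2), x[c(1, 3), ])
  expect_equal(complete_cases(x), x)
  x3 <- x; x3[, 1] <- NA
  expect_error(complete_cases(x3), "complete")
})

test_that("response CSV round-trips with empty-field missing markers", {
  gp <- mspss_parameters()
  y <- generate_responses(gp, 50, mode = "likert", seed = 6)
  y[3, 5] <- NA
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_responses(y, f)
  expect_equal(read_responses(f), y, ignore_attr = TRUE)
  expect_true(any(grepl(",,", readLines(f))))  # empty field, not "NA"
  bad <- y; bad[1, 1] <- 6
  write_responses(bad, f)
  expect_error(read_responses(f), "1..5")
  writeLines("q1,q2", f)
  expect_error(read_responses(f), "no respondent")
})
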