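# O(n^2) pair-enumeration oracle for tau-b, ties included
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

test_that("subscale totals sum four items and propagate missingness", {
  spec <- mspss_spec("three")
  y <- matrix(5, 3, 12, dimnames = list(NULL, spec$item_names))
  y[2, 1] <- NA
  y[3, ] <- 1
  sc <- subscale_scores(y, spec)
  expect_equal(unname(sc[1, ]), c(20, 20, 20))
  expect_true(is.na(sc[2, "SO"]) && !is.na(sc[2, "FA"]))
  expect_equal(unname(sc[3, ]), c(4, 4, 4))
  expect_error(subscale_scores(y + 0.5, spec), "integer")
})

test_that("kendall_tau handles the textbook cases", {
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(kendall_tau(x, x), 1)
  expect_equal(kendall_tau(x, -x), -1)
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("kendall_tau equals the pair-enumeration oracle with heavy ties", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    x <- sample(4:20, n, replace = TRUE)  # likert-total-like, many ties
    y <- pmin(pmax(x + sample(-6:6, n, replace = TRUE), 4), 20)
    expect_equal(kendall_tau(x, y), tau_b_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("the tau posterior recovers a known population value with decisive evidence", {
  # bivariate normal with grade correlation sin(pi tau / 2) has population
  # Kendall correlation tau; rank-based tau is invariant to the margins
  tau_pop <- -0.22
  rho <- sin(pi * tau_pop / 2)
  set.seed(31)
  n <- 3862
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  kb <- kendall_bayes(z1, z2)
  expect_equal(kb$post_mean, tau_pop, tolerance = 0.03 / 0.22)
  expect_gt(kb$log10_bf10, 2)
  expect_true(kb$ci[1] < tau_pop && tau_pop < kb$ci[2])
})

test_that("the Bayes factor favors the null for independent scores", {
  set.seed(41)
  under_one <- 0
  for (r in 1:5) {
    x <- rnorm(2000); y <- rnorm(2000)
    if (kendall_bayes(x, y)$bf10 < 1) under_one <- under_one + 1
  }
  expect_gte(under_one, 4)
})

test_that("tau inference is symmetric in its arguments and sign-equivariant", {
  set.seed(51)
  x <- sample(4:20, 300, replace = TRUE)
  y <- pmin(pmax(x + sample(-8:8, 300, replace = TRUE), 4), 20)
  a <- kendall_bayes(x, y); b <- kendall_bayes(y, x)
  expect_equal(a$bf10, b$bf10)
  expect_equal(a$tau, b$tau)
  flipped <- kendall_bayes(x, -y)
  expect_equal(flipped$tau, -a$tau)
  expect_equal(flipped$post_mean, -a$post_mean, tolerance = 1e-6)
  # perfect association: overwhelming evidence, interval excludes zero
  perf <- kendall_bayes(seq_len(50), seq_len(50))
  expect_gt(perf$log10_bf10, 5)
  expect_gt(perf$ci[1], 0)
  # pairwise exclusion drops incomplete pairs only
  xm <- x; xm[1:10] <- NA
  expect_equal(kendall_bayes(xm, y)$n, 290)
})

test_that("the validity report mirrors subscale-by-criterion structure", {
  spec <- mspss_spec("three")
  y <- generate_responses(mspss_parameters(), 400, mode = "likert",
                          seed = 61)
  sc <- subscale_scores(y, spec)
  set.seed(62)
  crit <- list(stress = -rowSums(y) + rnorm(400, sd = 10),
               control = rnorm(400))
  v <- validity_report(sc, crit)
  expect_equal(nrow(v), 6)
  expect_equal(unique(v$subscale), c("SO", "FA", "FR"))
  # convergent criterion correlates negatively for every subscale
  expect_true(all(v$tau[v$criterion == "stress"] < 0))
})
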