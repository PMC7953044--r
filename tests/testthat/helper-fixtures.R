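# Shared fixtures, computed once per test run and cached across test files.
# The large fixture mirrors the study conditions the generator encodes:
# n = 3868 continuous responses from the three-factor truth, fitted with the
# full chain protocol (3 chains, 1000 kept after 1000 warmup).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fixture_data_full <- function() {
  fixture("data_full",
          generate_responses(mspss_parameters(), 3868,
                             mode = "continuous", seed = 42))
}

fixture_fit_three_full <- function() {
  fixture("fit_three_full",
          bcfa(fixture_data_full(), mspss_spec("three"), seed = 7))
}

fixture_fit_one_full <- function() {
  fixture("fit_one_full",
          bcfa(fixture_data_full(), mspss_spec("one"), seed = 11))
}

# light fixture for module-level tests
fixture_data_small <- function() {
  fixture("data_small",
          generate_responses(mspss_parameters(), 1200,
                             mode = "continuous", seed = 101))
}

fixture_fit_three_small <- function() {
  fixture("fit_three_small",
          bcfa(fixture_data_small(), mspss_spec("three"), n_chains = 2,
               n_warmup = 300, n_kept = 300, sweeps = 5, seed = 13))
}

# random valid three-factor parameter point (for property-style tests)
random_params <- function(spec = mspss_spec("three")) {
  repeat {
    m <- spec$m
    fc <- diag(m)
    if (m > 1) {
      r <- stats::runif(m * (m - 1) / 2, -0.6, 0.6)
      fc[lower.tri(fc)] <- r
      fc[upper.tri(fc)] <- t(fc)[upper.tri(fc)]
      ev <- eigen(fc, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0.05) next
    }
    lambda <- stats::runif(spec$p, 0.4, 1.6)
    lambda[spec$is_ref] <- 1
    return(cfa_parameters(spec,
                          nu = stats::rnorm(spec$p, 4, 0.5),
                          lambda = lambda,
                          theta = stats::runif(spec$p, 0.2, 1),
                          factor_sd = stats::runif(m, 0.5, 1.5),
                          factor_corr = fc))
  }
}
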