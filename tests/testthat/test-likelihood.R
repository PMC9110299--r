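test_that("peak means anchor at the offsets and rise linearly in z", {
  expect_equal(fmc_peak_mean(0, 5, 0.04, 0.92), 0.04)
  expect_equal(fmc_peak_mean(10, 5, 0.04, 0.92), 0.92)
  expect_equal(fmc_peak_mean(5, 5, 0.04, 0.92), 0.48)
  x <- fmc_peak_mean(0:10, 5, 0.04, 0.92)
  expect_true(all(diff(x) > 0))
  expect_error(fmc_peak_mean(11, 5, 0.04, 0.92), "z must")
  expect_error(fmc_peak_mean(5, 5, 0.92, 0.04), "delta < epsilon")
})

test_that("peak log density matches an independent special-function formula", {
  # independent oracle: beta log-density written out in lgamma terms
  beta_lpdf <- function(b, a1, a2) {
    (a1 - 1) * log(b) + (a2 - 1) * log(1 - b) -
      (lgamma(a1) + lgamma(a2) - lgamma(a1 + a2))
  }
  expect_equal(fmc_beta_peak_logpdf(0.3, 5, 5, 0.04, 0.92, 100),
               beta_lpdf(0.3, 48, 52), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    b <- runif(1, 0.01, 0.99); z <- sample(0:10, 1); kap <- runif(1, 10, 500)
    x <- fmc_peak_mean(z, 5, 0.04, 0.92)
    expect_equal(fmc_beta_peak_logpdf(b, z, 5, 0.04, 0.92, kap),
                 beta_lpdf(b, kap * x, kap * (1 - x)), tolerance = 1e-10)
  }
  # kappa*x = kappa*(1-x) = 1 gives the uniform density
  expect_equal(fmc_beta_peak_logpdf(c(0.1, 0.5, 0.9), 5, 5, 0.25, 0.75, 2),
               rep(0, 3))
  # concentration: large kappa piles density onto the peak mean
  expect_gt(fmc_beta_peak_logpdf(0.48, 5, 5, 0.04, 0.92, 1e4),
            fmc_beta_peak_logpdf(0.2, 5, 5, 0.04, 0.92, 1e4) + 100)
  expect_error(fmc_beta_peak_logpdf(1, 5, 5, 0.04, 0.92, 10), "inside")
})

test_that("crypt log likelihood matches a naive double-loop oracle", {
  set.seed(7)
  b <- runif(10, 0.05, 0.95)
  kap <- runif(7, 50, 200)
  pz <- fmc_zdist(3, 0.8, 0.04, 0.06, 55)
  naive <- 0
  for (i in seq_along(b)) {
    mix <- 0
    for (z in 0:6) {
      x <- (0.92 - 0.04) * z / 6 + 0.04
      mix <- mix + pz[z + 1] *
        b[i]^(kap[z + 1] * x - 1) * (1 - b[i])^(kap[z + 1] * (1 - x) - 1) /
        beta(kap[z + 1] * x, kap[z + 1] * (1 - x))
    }
    naive <- naive + log(mix)
  }
  for (engine in c("r", "cpp")) {
    ll <- fmc_crypt_loglik(b, 55, 3, 0.8, 0.04, 0.06, 0.04, 0.92, kap,
                           engine = engine)
    expect_equal(ll, naive, tolerance = 1e-10)
  }
})

test_that("crypt log likelihood obeys independence and permutation symmetry", {
  set.seed(8)
  b <- runif(40, 0.02, 0.98)
  args <- list(age = 60, S = 4, lambda = 1, mu = 0.05, gamma = 0.05,
               delta = 0.04, epsilon = 0.92, kappa = 100)
  ll <- do.call(fmc_crypt_loglik, c(list(beta = b), args))
  ll_perm <- do.call(fmc_crypt_loglik, c(list(beta = rev(b)), args))
  ll_dup <- do.call(fmc_crypt_loglik, c(list(beta = c(b, b)), args))
  expect_equal(ll, ll_perm, tolerance = 1e-12)
  expect_equal(ll_dup, 2 * ll, tolerance = 1e-9)
  # single locus: log of the single mixture density
  one <- do.call(fmc_crypt_loglik, c(list(beta = b[1]), args))
  pz <- fmc_zdist(4, 1, 0.05, 0.05, 60)
  mix <- sum(pz * exp(fmc_beta_peak_logpdf(b[1], 0:8, 4, 0.04, 0.92, 100)))
  expect_equal(one, log(mix), tolerance = 1e-10)
})

test_that("the beta mixture integrates to one", {
  set.seed(9)
  for (i in 1:3) {
    S <- sample(3:6, 1)
    lambda <- runif(1, 0.2, 2); mu <- runif(1, 0.01, 0.2)
    gamma <- runif(1, 0.01, 0.2)
    delta <- runif(1, 0.01, 0.08); epsilon <- runif(1, 0.88, 0.97)
    kap <- runif(1, 50, 300)
    dens <- function(b)
      vapply(b, function(bi)
        exp(fmc_crypt_loglik(bi, 60, S, lambda, mu, gamma, delta, epsilon,
                             kap)), numeric(1))
    total <- stats::integrate(dens, 1e-8, 1 - 1e-8, rel.tol = 1e-9,
                              subdivisions = 500L)$value
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("boundary beta values are clamped with a warning", {
  expect_warning(out <- fmc_clamp_beta(c(0, 0.5, 1)), "clamped")
  expect_equal(out, c(1e-6, 0.5, 1 - 1e-6))
  expect_identical(fmc_clamp_beta(c(0.2, 0.8)), c(0.2, 0.8))
  expect_error(fmc_clamp_beta(c(0.2, 1.2)), "\\[0, 1\\]")
})
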