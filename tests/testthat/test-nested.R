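test_that("a constant likelihood returns zero log evidence", {
  # the evidence of a normalised prior under L = 1 is exactly 1
  ns <- fmc_nested(runif(5, 0.1, 0.9), 60, 3, nlive = 100, walks = 10,
                   seed = 1, loglik = function(p) 0)
  expect_lt(abs(ns$logz), 0.01)
  expect_equal(sum(exp(ns$logwt)), 1, tolerance = 1e-8)
})

test_that("nested sampling is deterministic given the seed", {
  set.seed(21)
  b <- fmc_clamp_beta(fmc_simulate_crypt(n_loci = 40, seed = 22)$beta)
  a <- fmc_nested(b, 60, 3, nlive = 50, walks = 10, seed = 33)
  b2 <- fmc_nested(b, 60, 3, nlive = 50, walks = 10, seed = 33)
  expect_identical(a$logz, b2$logz)
  expect_identical(a$samples, b2$samples)
  c2 <- fmc_nested(b, 60, 3, nlive = 50, walks = 10, seed = 34)
  expect_false(identical(a$logz, c2$logz))
})

test_that("evidence combination is a softmax with closed-form cases", {
  mk <- function(S, logz, err = 0.1)
    structure(list(S = S, logz = logz, logzerr = err), class = "fmc_nested")
  one <- fmc_combine_evidence(list(mk(4L, -3)))
  expect_equal(one$prob, 1)
  two <- fmc_combine_evidence(list(mk(3L, 5), mk(4L, 5)))
  expect_equal(two$prob, c(0.5, 0.5))
  three <- fmc_combine_evidence(list(mk(3L, 0), mk(4L, log(3))))
  expect_equal(three$prob, c(0.25, 0.75))
  expect_lt(abs(sum(three$prob) - 1), 1e-12)
  expect_true(all(three$prob_sd > 0))
  expect_error(fmc_combine_evidence(list(mk(3L, 0), mk(3L, 1))), "duplicate")
})

test_that("model-averaged resampling respects P(S | beta)", {
  set.seed(23)
  mk <- function(S, logz) {
    sm <- matrix(runif(200 * (8 + 2 * S)), 200)
    colnames(sm) <- fmc_param_names(S)
    structure(list(S = S, logz = logz, logzerr = 0.1, samples = sm,
                   logwt = rep(log(1 / 200), 200)), class = "fmc_nested")
  }
  res <- list(mk(3L, 0), mk(4L, log(3)))
  ev <- fmc_combine_evidence(res)
  post <- fmc_combined_posterior(res, ev, n = 1e5)
  frac4 <- mean(post[, "S"] == 4)
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(frac4 - 0.75), 3 * se)
  # degenerate P(S): every sample carries that S
  only <- fmc_combined_posterior(res[2], fmc_combine_evidence(res[2]),
                                 n = 500)
  expect_true(all(only[, "S"] == 4))
  # kappa columns beyond a draw's own S stay NA
  expect_true(all(is.na(post[post[, "S"] == 3, "kappa_8"])))
})

test_that("rank-normalized split R-hat separates converged from split chains", {
  set.seed(24)
  same <- matrix(rnorm(4000), 1000, 4)
  rh <- fmc_rhat(same)
  expect_lt(rh, 1.01)
  ident <- matrix(rep(rnorm(1000), 2), 1000, 2)
  expect_lt(fmc_rhat(ident), 1.001)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(fmc_rhat(apart), 1.1)
  # array input returns one value per parameter
  arr <- array(rnorm(1000 * 2 * 3), c(1000, 2, 3),
               dimnames = list(NULL, NULL, c("a", "b", "c")))
  expect_named(fmc_rhat(arr), c("a", "b", "c"))
  expect_error(fmc_rhat(matrix(1:10, 10, 1)), ">= 2")
  expect_error(fmc_rhat(matrix(1:6, 3, 2)), ">= 4")
})

test_that("posterior predictive density normalises and tracks single draws", {
  set.seed(25)
  S <- 3
  pars <- fmc_prior_transform(runif(8 + 2 * S, 0.3, 0.7), S)
  sm <- matrix(pars, 1, dimnames = list(NULL, names(pars)))
  grid <- seq(0.001, 0.999, length.out = 500)
  dens <- fmc_predictive_density(sm, age = 60, grid = grid, S = 3)
  # single draw: equals that draw's own mixture density
  direct <- vapply(grid, function(b)
    exp(fmc_crypt_loglik(b, 60, S, pars["lambda"], pars["mu"], pars["gamma"],
                         pars["delta"], pars["epsilon"],
                         pars[paste0("kappa_", 0:6)])), numeric(1))
  expect_equal(dens, direct, tolerance = 1e-8)
  # integrates to 1 (quadrature over the evaluation grid)
  two <- rbind(cbind(S = 3, t(pars))[, c("S", names(pars))],
               cbind(S = 3, t(pars))[, c("S", names(pars))])
  dens2 <- fmc_predictive_density(two, age = 60, grid = grid)
  expect_lt(abs(sum(dens2) * diff(grid)[1] - 1), 1e-3)
})
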