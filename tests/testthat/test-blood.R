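test_that("blood panel selection keeps loci with mean beta in [0.40, 0.60]", {
  beta <- matrix(c(0.39, 0.40, 0.50, 0.60, 0.61), 5, 2,
                 dimnames = list(paste0("cg", 1:5), c("s1", "s2")))
  expect_equal(fmc_blood_panel(beta), c("cg2", "cg3", "cg4"))
  all_half <- matrix(0.5, 3, 4, dimnames = list(paste0("cg", 1:3), NULL))
  expect_length(fmc_blood_panel(all_half), 3)
})

test_that("sample variance is the population variance with a naive oracle", {
  expect_equal(fmc_sample_variance(rep(0.5, 10)), 0)
  expect_equal(fmc_sample_variance(c(rep(0, 5), rep(1, 5))), 0.25)
  set.seed(61)
  x <- runif(500)
  naive <- sum((x - sum(x) / length(x))^2) / length(x)
  expect_equal(fmc_sample_variance(x), naive, tolerance = 1e-12)
})

test_that("the W-shape score separates trimodal from central distributions", {
  central <- rep(0.5, 1000) + seq(-0.02, 0.02, length.out = 1000)
  ws <- fmc_w_shape(central)
  expect_equal(ws$outer_frac, 0)
  set.seed(62)
  tri <- c(rnorm(250, 0.05, 0.02), rnorm(500, 0.5, 0.03),
           rnorm(250, 0.95, 0.02))
  tri <- pmin(pmax(tri, 0.001), 0.999)
  ws2 <- fmc_w_shape(tri)
  expect_equal(ws2$outer_frac, 0.5, tolerance = 0.05)
  expect_equal(ws2$n_peaks, 3)
})

test_that("polyclonal blood keeps a low, stable variance", {
  sim <- fmc_simulate_hematopoiesis(n_lineages = 1000, n_loci = 1000,
                                    clone_final_fraction = 0, seed = 63,
                                    times = seq(10, 70, by = 20))
  expect_true(all(sim$clone_fraction == 0))
  expect_lt(max(sim$variance), 0.005)
  expect_lt(max(sim$variance) - min(sim$variance), 0.002)
})

test_that("bulk variance rises monotonically with the final clone fraction", {
  vs <- vapply(c(0, 0.3, 0.6, 0.9), function(f) {
    sim <- fmc_simulate_hematopoiesis(n_lineages = 500, n_loci = 1500,
                                      clone_final_fraction = f,
                                      clone_growth_rate = 5,
                                      clone_start = 50,
                                      times = c(55), seed = 64)
    sim$variance[1]
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("rapid expansions are W-shaped, slow expansions are not", {
  fast <- fmc_simulate_hematopoiesis(n_lineages = 500, n_loci = 2000,
                                     clone_final_fraction = 0.9,
                                     clone_growth_rate = 8,
                                     clone_start = 50, times = c(52),
                                     seed = 65)
  # chronic-like: expansion spread over about a decade, so within-clone
  # fluctuations have partly desynchronised by observation
  slow <- fmc_simulate_hematopoiesis(n_lineages = 500, n_loci = 2000,
                                     clone_final_fraction = 0.9,
                                     clone_growth_rate = 0.5,
                                     clone_start = 50, times = c(62),
                                     seed = 65)
  wf <- fmc_w_shape(fast$beta[, 1])
  ws <- fmc_w_shape(slow$beta[, 1])
  expect_gt(wf$outer_frac, 0.3)
  expect_gte(wf$n_peaks, 3)
  expect_lt(ws$outer_frac, 0.1)
  # both carry more variance than a polyclonal baseline
  base <- fmc_simulate_hematopoiesis(n_lineages = 500, n_loci = 2000,
                                     clone_final_fraction = 0, times = c(60),
                                     seed = 65)
  expect_gt(ws$frac_mid, 0.9)
  expect_gt(slow$variance[1], base$variance[1])
  expect_gt(fast$variance[1], slow$variance[1])
})

test_that("a frozen founder clone at full take-over is three-point distributed", {
  sim <- fmc_simulate_hematopoiesis(n_lineages = 300, n_loci = 1000,
                                    mu = 1e-4, gamma = 1e-4,
                                    clone_final_fraction = 0.999,
                                    clone_growth_rate = 20,
                                    clone_start = 30, times = c(31),
                                    seed = 66)
  b <- sim$beta[, 1]
  near <- vapply(b, function(x) min(abs(x - c(0, 0.5, 1))), numeric(1))
  expect_lt(max(near), 0.05)
})
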