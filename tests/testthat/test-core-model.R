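test_that("state enumeration matches the (S+1)(S+2)/2 count and ordering", {
  st <- fmc_states(2)
  expect_equal(st$n_states, 6L)
  expect_equal(cbind(st$k, st$m),
               cbind(c(0L, 1L, 2L, 0L, 1L, 0L), c(0L, 0L, 0L, 1L, 1L, 2L)))
  for (S in c(3L, 5L, 12L)) {
    st <- fmc_states(S)
    expect_equal(st$n_states, (S + 1) * (S + 2) / 2)
    expect_equal(length(st$k), st$n_states)
    expect_false(anyDuplicated(paste(st$k, st$m)) > 0)
    expect_true(all(st$k + st$m <= S))
  }
  expect_error(fmc_states(1), "S must be")
  expect_error(fmc_states(2.5), "S must be")
})

test_that("transition rates follow the master-equation neighbour classes", {
  # the worked replacement example: of S(S-1) = 20 ordered pairs only one
  # turns (3,1) into (3,2), so the rate is lambda*S / 20 = lambda / 4
  expect_equal(fmc_transition_rate(c(3, 1), c(3, 2), 5, 1, 0, 0), 0.25)
  expect_equal(fmc_transition_rate(c(3, 1), c(3, 2), 5, 2, 0, 0), 0.5)
  # all processes off
  expect_equal(fmc_transition_rate(c(1, 0), c(2, 0), 5, 0, 0, 0), 0)
  # 2S unmethylated alleles, any one methylates: (0,0) -> (1,0) at 2S*mu
  expect_equal(fmc_transition_rate(c(0, 0), c(1, 0), 5, 0, 0.05, 0), 0.5)
  # demethylation of a het cell: (k,m) -> (k-1,m) carries k*gamma
  expect_equal(fmc_transition_rate(c(2, 1), c(1, 1), 5, 0, 0, 0.1), 0.2)
  # double demethylation of hom-meth cells: (k,m) -> (k+1,m-1) at 2m*gamma
  expect_equal(fmc_transition_rate(c(1, 2), c(2, 1), 5, 0, 0, 0.1), 0.4)
  # non-neighbour transitions are forbidden
  expect_equal(fmc_transition_rate(c(0, 0), c(2, 0), 5, 1, 1, 1), 0)
  expect_equal(fmc_transition_rate(c(0, 0), c(0, 2), 5, 1, 1, 1), 0)
  expect_error(fmc_transition_rate(c(4, 2), c(4, 3), 5, 1, 0, 0), "state")
  expect_error(fmc_transition_rate(c(1, 0), c(1, 0), 5, 1, 0, 0), "differ")
})

test_that("generator diagonal equals the symbolic loss term and columns sum to 0", {
  st <- fmc_states(5)
  Tm <- fmc_generator(5, 1, 0.05, 0.05, states = st)
  i31 <- which(st$k == 3 & st$m == 1)
  # loss term: 2(k(S-k) + m(S-k-m)) lambda/(S-1) + (2S-(k+2m)) mu + (k+2m) gamma
  expect_equal(Tm[i31, i31], -(2 * (3 * 2 + 1 * 1) * 1 / 4 + 5 * 0.05 + 5 * 0.05))
  # diagonal must equal minus the summed off-diagonal outflows, evaluated
  # independently through fmc_transition_rate
  for (i in seq_len(st$n_states)) {
    out <- 0
    for (j in seq_len(st$n_states)) {
      if (i == j) next
      out <- out + fmc_transition_rate(c(st$k[i], st$m[i]),
                                       c(st$k[j], st$m[j]), 5, 1, 0.05, 0.05)
      expect_equal(Tm[j, i],
                   fmc_transition_rate(c(st$k[i], st$m[i]),
                                       c(st$k[j], st$m[j]), 5, 1, 0.05, 0.05))
    }
    expect_equal(Tm[i, i], -out)
  }
  expect_equal(fmc_generator(2, 0, 0, 0), matrix(0, 6, 6),
               ignore_attr = TRUE)
  set.seed(11)
  for (S in 2:20) {
    r <- runif(3, 0, 2)
    Tm <- fmc_generator(S, r[1], r[2], r[3])
    expect_lt(max(abs(colSums(Tm))), 1e-12)
  }
})

test_that("initial condition puts half the mass on each clonal state", {
  for (S in c(2, 5)) {
    st <- fmc_states(S)
    p0 <- fmc_initial(st)
    expect_equal(sum(p0), 1)
    expect_equal(sum(p0 > 0), 2)
    expect_equal(p0[st$k == 0 & st$m == 0], 0.5)
    expect_equal(p0[st$k == 0 & st$m == S], 0.5)
  }
})

test_that("propagation preserves mass, handles t = 0 and the frozen limit", {
  st <- fmc_states(4)
  p0 <- fmc_initial(st)
  Tm <- fmc_generator(4, 1, 0.05, 0.05, states = st)
  expect_identical(fmc_propagate(p0, Tm, 0), p0)
  T0 <- fmc_generator(4, 0, 0, 0, states = st)
  expect_equal(fmc_propagate(p0, T0, 123), p0)
  for (t in c(0.1, 1, 10, 100)) {
    p <- fmc_propagate(p0, Tm, t)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
  }
  expect_error(fmc_propagate(p0, Tm, -1), "non-negative")
})

test_that("without replacement the long-time z-distribution is binomial", {
  # lambda = 0 decouples alleles into independent flip-flops with
  # stationary methylation probability mu/(mu+gamma)
  pz <- fmc_zdist(2, 0, 0.05, 0.05, 500)
  expect_equal(pz, dbinom(0:4, 4, 0.5), tolerance = 1e-9)
  pz2 <- fmc_zdist(3, 0, 0.06, 0.02, 800)
  expect_equal(pz2, dbinom(0:6, 6, 0.75), tolerance = 1e-6)
})

test_that("marginalisation sums states on z = k + 2m", {
  st <- fmc_states(2)
  pz <- fmc_marginal_z(rep(1 / 6, 6), st)
  expect_equal(pz, c(1, 1, 2, 1, 1) / 6)
  st5 <- fmc_states(5)
  pz0 <- fmc_marginal_z(fmc_initial(st5), st5)
  expect_equal(pz0[c(1, 11)], c(0.5, 0.5))
  expect_equal(sum(pz0), 1)
})

test_that("slow-fluctuation regime stays clonal and bimodal", {
  pz <- fmc_zdist(5, 1, 5e-4, 5e-4, 60)
  expect_gt(pz[1] + pz[11], 0.9)
})

test_that("slow-rate quasi-stationary peaks are in 1:2:1 proportion", {
  # multiplicity of the clonal heterozygous state: at quasi-stationarity the
  # z = S peak holds about twice the mass of the z = 0 or z = 2S peaks
  pz <- fmc_zdist(4, 1, 1e-4, 1e-4, 5e4)
  expect_equal(pz[5] / pz[1], 2, tolerance = 0.1)
  expect_equal(pz[5] / pz[9], 2, tolerance = 0.1)
})

test_that("fast-fluctuation limit approaches Binomial(2S, 1/2)", {
  pz <- fmc_zdist(5, 1, 20, 20, 60)
  tv <- 0.5 * sum(abs(pz - dbinom(0:10, 10, 0.5)))
  expect_lt(tv, 0.02)
})

test_that("swapping mu and gamma reflects the z-distribution", {
  for (t in c(5, 60)) {
    a <- fmc_zdist(5, 1, 0.08, 0.02, t)
    b <- fmc_zdist(5, 1, 0.02, 0.08, t)
    expect_lt(max(abs(a - rev(b))), 1e-9)
  }
})

test_that("compiled z-distribution agrees with the plain-R path", {
  set.seed(3)
  for (S in c(2L, 5L, 8L)) {
    r <- runif(3, 0, 1.5)
    a <- fmc_zdist(S, r[1], r[2], r[3], 47)
    b <- fmclock:::cpp_zdist(S, r[1], r[2], r[3], 47)
    expect_equal(a, as.numeric(b), tolerance = 1e-10)
  }
})
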