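# Shared fixtures, built in code. Expensive objects are memoised so several
# test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The "just right" validation crypt: S = 5, lambda = 1, mu = gamma = 0.05,
# age 60, 1794 loci, noise delta = 0.04, epsilon = 0.92, kappa = 100.
just_right_crypt <- function() {
  memoise_fixture("just_right_crypt", function() {
    fmc_simulate_crypt(S = 5, lambda = 1, mu = 0.05, gamma = 0.05,
                       age = 60, n_loci = 1794, delta = 0.04,
                       epsilon = 0.92, kappa = 100, seed = 20211)
  })
}

# Four independently seeded full inferences of the just-right crypt over
# S in [3, 8]. Shared between the parameter-recovery and convergence tests.
just_right_fits <- function() {
  memoise_fixture("just_right_fits", function() {
    crypt <- just_right_crypt()
    lapply(1:4, function(i) {
      fmc_fit(crypt$beta, age = 60, S = 3:8, nlive = 200, walks = 20,
              seed = 100 + i)
    })
  })
}

# A small cohort with planted fluctuating loci for the selection pipeline:
# 3 individuals x 4 crypts, 200 fluctuating + 1800 constant loci.
planted_cohort <- function() {
  memoise_fixture("planted_cohort", function() {
    set.seed(4821)
    n_fluct <- 200; n_const <- 1800; n_samp <- 12
    individual <- rep(paste0("ind", 1:3), each = 4)
    fluct <- sapply(seq_len(n_samp), function(j) {
      crypt <- fmc_simulate_crypt(S = 5, lambda = 1, mu = 0.05,
                                  gamma = 0.05, age = 60,
                                  n_loci = n_fluct, kappa = 100)
      crypt$beta
    })
    const_level <- runif(n_const, 0.05, 0.95)
    const <- sapply(seq_len(n_samp), function(j) {
      pmin(pmax(const_level + rnorm(n_const, 0, 0.005), 1e-4), 1 - 1e-4)
    })
    beta <- rbind(fluct, const)
    rownames(beta) <- c(sprintf("cg%07d", seq_len(n_fluct)),
                        sprintf("cg%07d", 5e6 + seq_len(n_const)))
    colnames(beta) <- paste0("crypt", seq_len(n_samp))
    list(beta = beta, individual = individual,
         planted = rownames(beta)[seq_len(n_fluct)])
  })
}

# A toy probe manifest in which one probe fails each filter and one passes
# them all.
toy_manifest <- function() {
  data.frame(
    probe_id = paste0("cg", 1:6),
    design_type = c("I", "II", "II", "II", "II", "II"),
    chr = c("chr1", "chrX", "chr2", "chr3", "chr4", "chr5"),
    cross_reactive = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    island_relation = c("OpenSea", "OpenSea", "OpenSea", "Island",
                        "OpenSea", "OpenSea"),
    stringsAsFactors = FALSE)
}
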