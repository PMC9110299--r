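#' Gillespie simulation of the stem cell niche
#'
#' Exact stochastic simulation of one niche of `S` stem cells carrying
#' `n_loci` fCpG loci. Replacement events occur at total rate `lambda * S`;
#' the replaced cell adopts the replacer's entire (linked) epigenotype. In
#' the `"well_mixed"` geometry the replaced cell is a uniform choice among
#' the other `S - 1` cells; in the `"ring"` geometry a random cell
#' overwrites a random one of its two ring neighbours. Each unmethylated
#' allele of a non-frozen locus methylates at rate `mu` and each methylated
#' allele demethylates at rate `gamma`, independently across loci. Every
#' locus starts clonal: all cells homozygously methylated or unmethylated
#' with probability 1/2 each. A stated fraction of loci can be frozen at
#' their initial clonal state (non-fluctuating contaminants).
#'
#' With `linked = FALSE` each locus instead lives in its own independent
#' niche, which is the sampling regime matched by the analytic
#' master-equation model ([fmc_zdist()]).
#'
#' @param S stem cell number (>= 2).
#' @param lambda,mu,gamma niche rates per year.
#' @param t duration in years.
#' @param n_loci number of fCpG loci.
#' @param geometry `"well_mixed"` or `"ring"` (linked simulation only).
#' @param frozen_fraction fraction of loci frozen at their clonal initial
#'   state.
#' @param linked simulate loci linked within one niche (`TRUE`, the
#'   biological situation) or as independent replicate niches (`FALSE`).
#' @param seed optional integer seed.
#' @return Integer vector of per-locus methylated-allele counts
#'   `z` in `0..2S`, with attribute `frozen` (logical) when
#'   `frozen_fraction > 0`.
#' @examples
#' z <- fmc_simulate_niche(5, 1, 0.05, 0.05, t = 60, n_loci = 100, seed = 1)
#' table(z)
#' @export
fmc_simulate_niche <- function(S, lambda, mu, gamma, t, n_loci,
                               geometry = c("well_mixed", "ring"),
                               frozen_fraction = 0, linked = TRUE,
                               seed = NULL) {
  S <- check_S(S)
  check_rates(lambda, mu, gamma)
  geometry <- match.arg(geometry)
  stopifnot(t >= 0, n_loci >= 1, frozen_fraction >= 0, frozen_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!linked) {
    if (frozen_fraction > 0)
      stop("frozen loci require linked = TRUE", call. = FALSE)
    return(as.integer(cpp_sim_independent(S, lambda, mu, gamma, t,
                                          as.integer(n_loci),
                                          geometry == "ring")))
  }
  init <- 2L * rbinom(n_loci, 1L, 0.5)
  n_frozen <- round(frozen_fraction * n_loci)
  frozen <- rep(FALSE, n_loci)
  if (n_frozen > 0) frozen[sample.int(n_loci, n_frozen)] <- TRUE
  z <- as.integer(cpp_sim_niche(S, lambda, mu, gamma, t, init, frozen,
                                geometry == "ring"))
  if (n_frozen > 0) attr(z, "frozen") <- frozen
  z
}

#' Add array measurement noise to latent methylation levels
#'
#' Converts latent methylated-allele counts `z` into noisy array beta
#' values: `beta_i ~ Beta(kappa * x_i, kappa * (1 - x_i))` with peak mean
#' `x_i = (epsilon - delta) * z_i / (2S) + delta`. Defaults reproduce the
#' noise-injection settings used to make master-equation output comparable
#' to real arrays: offsets `delta = 0.04` and `epsilon = 0.92`, sample size
#' `kappa = 1000`.
#'
#' @param z integer vector of methylated-allele counts in `0..2S`.
#' @param S stem cell number.
#' @param delta,epsilon array offsets.
#' @param kappa beta sample-size parameter; a scalar, or a vector of
#'   `2S + 1` per-peak values indexed by `z`.
#' @param seed optional integer seed.
#' @return Numeric vector of beta values in (0, 1).
#' @export
fmc_add_noise <- function(z, S, delta = 0.04, epsilon = 0.92, kappa = 1000,
                          seed = NULL) {
  S <- check_S(S)
  if (any(z < 0) || any(z > 2 * S)) stop("z out of range", call. = FALSE)
  if (any(kappa <= 0)) stop("kappa must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kap <- if (length(kappa) == 1L) rep(kappa, length(z))
         else kappa[z + 1L]
  x <- fmc_peak_mean(z, S, delta, epsilon)
  rbeta(length(z), kap * x, kap * (1 - x))
}

#' Generate a complete synthetic crypt
#'
#' Composition of [fmc_simulate_niche()] and [fmc_add_noise()]: simulates
#' the niche to the donor's age and overlays array noise, returning both
#' the beta vector and a provenance record of the generating parameters.
#' The defaults are the "just right" validation settings: `S = 5`,
#' `lambda = 1`, `mu = gamma = 0.05`, noise offsets `delta = 0.04`,
#' `epsilon = 0.92` and peak sample size `kappa = 100`.
#'
#' @inheritParams fmc_simulate_niche
#' @param age donor age in years.
#' @param delta,epsilon,kappa noise parameters, see [fmc_add_noise()].
#' @return A list of class `"fmc_crypt"`: `beta`, latent `z`, and `truth`
#'   (named list of every generating parameter).
#' @examples
#' crypt <- fmc_simulate_crypt(seed = 1)
#' hist(crypt$beta, breaks = 50)
#' @export
fmc_simulate_crypt <- function(S = 5, lambda = 1.0, mu = 0.05, gamma = 0.05,
                               age = 60, n_loci = 1794, delta = 0.04,
                               epsilon = 0.92, kappa = 100,
                               geometry = c("well_mixed", "ring"),
                               frozen_fraction = 0, seed = NULL) {
  geometry <- match.arg(geometry)
  if (!is.null(seed)) set.seed(seed)
  z <- fmc_simulate_niche(S, lambda, mu, gamma, t = age, n_loci = n_loci,
                          geometry = geometry,
                          frozen_fraction = frozen_fraction)
  beta <- fmc_add_noise(z, S, delta = delta, epsilon = epsilon,
                        kappa = kappa)
  structure(
    list(beta = beta, z = as.integer(z),
         truth = list(S = S, lambda = lambda, mu = mu, gamma = gamma,
                      age = age, n_loci = n_loci, delta = delta,
                      epsilon = epsilon, kappa = kappa, geometry = geometry,
                      frozen_fraction = frozen_fraction, seed = seed)),
    class = "fmc_crypt")
}

#' @exportS3Method print fmc_crypt
print.fmc_crypt <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "Synthetic crypt: %d loci, S = %d, lambda = %.3g, mu = %.3g, gamma = %.3g, age = %.3g\n",
    tr$n_loci, tr$S, tr$lambda, tr$mu, tr$gamma, tr$age))
  invisible(x)
}
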