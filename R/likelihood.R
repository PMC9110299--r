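#' Mean array beta value of the latent methylation peak
#'
#' Arrays never report exactly 0 or 1: unmethylated loci read slightly above
#' 0 (background offset `delta`) and fully methylated loci slightly below 1
#' (saturation offset `epsilon`). The mean beta value of the peak for `z`
#' methylated alleles of `2S` is the linear transform
#' `x = (epsilon - delta) * z / (2S) + delta`.
#'
#' @param z methylated-allele count, `0 <= z <= 2S` (vectorised).
#' @param S stem cell number.
#' @param delta,epsilon offsets, `0 < delta < epsilon < 1`.
#' @return Peak mean(s) in `(0, 1)`, strictly increasing in `z`.
#' @examples
#' fmc_peak_mean(5, S = 5, delta = 0.04, epsilon = 0.92)  # 0.48
#' @export
fmc_peak_mean <- function(z, S, delta, epsilon) {
  S <- check_S(S)
  if (!(delta > 0 && delta < epsilon && epsilon < 1))
    stop("need 0 < delta < epsilon < 1", call. = FALSE)
  if (any(z < 0) || any(z > 2 * S))
    stop("z must lie in [0, 2S]", call. = FALSE)
  (epsilon - delta) * z / (2 * S) + delta
}

#' Log density of a measured beta value around one methylation peak
#'
#' Measured beta values around the peak for `z` methylated alleles are
#' modelled as Beta(kappa_z * x, kappa_z * (1 - x)) with `x` the peak mean
#' from [fmc_peak_mean()] and `kappa_z` a peak-specific scale ("sample
#' size") parameter.
#'
#' @param beta measured beta value(s), strictly inside (0, 1).
#' @inheritParams fmc_peak_mean
#' @param kappa peak scale parameter, > 0.
#' @return Log density value(s).
#' @export
fmc_beta_peak_logpdf <- function(beta, z, S, delta, epsilon, kappa) {
  if (any(beta <= 0) || any(beta >= 1))
    stop("beta values must lie strictly inside (0, 1)", call. = FALSE)
  if (any(kappa <= 0)) stop("kappa must be positive", call. = FALSE)
  x <- fmc_peak_mean(z, S, delta, epsilon)
  dbeta(beta, kappa * x, kappa * (1 - x), log = TRUE)
}

#' Clamp beta values away from the boundary
#'
#' The beta density is undefined at exactly 0 or 1; array noise makes such
#' values rare but possible. Values outside `[eps, 1 - eps]` are clamped
#' with a warning reporting how many were affected.
#'
#' @param beta numeric vector of beta values in `[0, 1]`.
#' @param eps clamp width (default `1e-6`).
#' @return Clamped vector.
#' @export
fmc_clamp_beta <- function(beta, eps = 1e-6) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  n_bad <- sum(beta < eps | beta > 1 - eps)
  if (n_bad > 0)
    warning(n_bad, " beta value(s) clamped to [", eps, ", ", 1 - eps, "]",
            call. = FALSE)
  pmin(pmax(beta, eps), 1 - eps)
}

#' Log likelihood of one crypt under the full model
#'
#' The loci are assumed independent given the niche dynamics, so the crypt
#' log likelihood is `sum_i log sum_z P(beta_i | z, delta, epsilon,
#' kappa_z) * P(z | lambda, mu, gamma; t = age)`. The latent
#' `z`-distribution is computed once per call (one matrix exponential), not
#' per locus, and the mixture is accumulated by log-sum-exp.
#'
#' @param beta vector of fCpG beta values, strictly inside (0, 1).
#' @param age donor age in years (the elapsed time of the master equation).
#' @param S stem cell number.
#' @param lambda,mu,gamma niche rates (per year).
#' @param delta,epsilon array offsets.
#' @param kappa vector of `2S + 1` peak scales (or a scalar recycled).
#' @param engine `"cpp"` (default, compiled path) or `"r"` (plain R
#'   reference path; slower, used for cross-checks).
#' @return Single log-likelihood value.
#' @export
fmc_crypt_loglik <- function(beta, age, S, lambda, mu, gamma,
                             delta, epsilon, kappa, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  S <- check_S(S)
  if (length(age) != 1L || age <= 0)
    stop("age must be a single positive number of years", call. = FALSE)
  nz <- 2 * S + 1
  if (length(kappa) == 1L) kappa <- rep(kappa, nz)
  if (length(kappa) != nz)
    stop("kappa must have length 2S + 1 (or be scalar)", call. = FALSE)
  if (any(beta <= 0) || any(beta >= 1))
    stop("beta values must lie strictly inside (0, 1); see fmc_clamp_beta()",
         call. = FALSE)
  if (engine == "cpp") {
    pars <- c(lambda, mu, gamma, delta, epsilon, 1, 1, kappa)
    return(cpp_loglik(log(beta), log1p(-beta), age, S, pars))
  }
  pz <- fmc_zdist(S, lambda, mu, gamma, age)
  comp <- vapply(0:(2 * S), function(z) {
    lw <- if (pz[z + 1] > 0) log(pz[z + 1]) else -Inf
    lw + fmc_beta_peak_logpdf(beta, z, S, delta, epsilon, kappa[z + 1])
  }, numeric(length(beta)))
  comp <- matrix(comp, nrow = length(beta))
  mx <- apply(comp, 1, max)
  sum(mx + log(rowSums(exp(comp - mx))))
}

#' Posterior predictive beta-mixture density
#'
#' Averages the beta-mixture density over posterior parameter draws,
#' producing the predictive density curve overlaid on crypt beta histograms.
#'
#' @param samples matrix of posterior draws; columns must include the
#'   parameters named by [fmc_param_names()] for the draw's `S`, plus a
#'   column `S` when draws mix several stem cell numbers.
#' @param age donor age in years.
#' @param grid beta values at which to evaluate the density.
#' @param S stem cell number, used when `samples` has no `S` column.
#' @return Numeric vector of predictive densities over `grid`.
#' @export
fmc_predictive_density <- function(samples, age, grid = seq(0.001, 0.999,
                                                            length.out = 200),
                                   S = NULL) {
  if (nrow(samples) < 1L) stop("need at least one posterior draw")
  has_S <- "S" %in% colnames(samples)
  dens <- matrix(0, nrow(samples), length(grid))
  for (j in seq_len(nrow(samples))) {
    Sj <- if (has_S) samples[j, "S"] else S
    if (is.null(Sj)) stop("S column missing and S not supplied")
    nz <- 2 * Sj + 1
    kap <- samples[j, paste0("kappa_", 0:(2 * Sj))]
    pz <- fmc_zdist(Sj, samples[j, "lambda"], samples[j, "mu"],
                    samples[j, "gamma"], age)
    x <- fmc_peak_mean(0:(2 * Sj), Sj, samples[j, "delta"],
                       samples[j, "epsilon"])
    for (z in seq_len(nz))
      dens[j, ] <- dens[j, ] +
        pz[z] * dbeta(grid, kap[z] * x[z], kap[z] * (1 - x[z]))
  }
  colMeans(dens)
}
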