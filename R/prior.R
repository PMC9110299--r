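#' Prior specification for the crypt model
#'
#' Collects the prior scales used by the Bayesian inference. The rate
#' parameters are naturally positive and carry half-normal priors: the
#' replacement-rate scale of 1 per stem cell per year follows published
#' lineage-tracing estimates of roughly 1.3 replacements per stem cell per
#' year, and the (de)methylation scale of 0.05 per allele per year follows
#' from a methylation error rate of about 1e-3 per division with stem cells
#' dividing roughly every 3 days. The array offsets `delta` and `epsilon`
#' carry beta priors with prior means 0.05 and 0.95. The per-peak beta
#' scale parameters `kappa_z` are hierarchical lognormal with population
#' mean `theta` and s.d. `sigma`, themselves half-normal with scales 500
#' and 50.
#'
#' @param lambda_scale,mu_scale,gamma_scale half-normal scales (the sigma of
#'   the underlying normal) for the replacement, methylation and
#'   demethylation rates.
#' @param delta_shape,epsilon_shape beta shape pairs for the background and
#'   saturation offsets.
#' @param theta_scale,sigma_scale half-normal scales for the kappa
#'   hyperparameters.
#' @return An object of class `"fmc_prior"`.
#' @export
fmc_prior <- function(lambda_scale = 1.0, mu_scale = 0.05, gamma_scale = 0.05,
                      delta_shape = c(5, 95), epsilon_shape = c(95, 5),
                      theta_scale = 500, sigma_scale = 50) {
  stopifnot(lambda_scale > 0, mu_scale > 0, gamma_scale > 0,
            all(delta_shape > 0), all(epsilon_shape > 0),
            theta_scale > 0, sigma_scale > 0)
  structure(list(lambda_scale = lambda_scale, mu_scale = mu_scale,
                 gamma_scale = gamma_scale, delta_shape = delta_shape,
                 epsilon_shape = epsilon_shape, theta_scale = theta_scale,
                 sigma_scale = sigma_scale),
            class = "fmc_prior")
}

prior_config_vector <- function(prior) {
  c(prior$lambda_scale, prior$mu_scale, prior$gamma_scale,
    prior$delta_shape, prior$epsilon_shape,
    prior$theta_scale, prior$sigma_scale)
}

#' Parameter vector layout
#'
#' The sampled parameter vector for a niche of `S` stem cells is
#' `(lambda, mu, gamma, delta, epsilon, theta, sigma, kappa_0, ..., kappa_2S)`
#' with dimension `8 + 2S`.
#'
#' @param S stem cell number.
#' @return Character vector of parameter names.
#' @export
fmc_param_names <- function(S) {
  c("lambda", "mu", "gamma", "delta", "epsilon", "theta", "sigma",
    paste0("kappa_", 0:(2 * S)))
}

dhalfnorm_log <- function(x, scale) {
  ifelse(x < 0, -Inf,
         log(2) + stats::dnorm(x, 0, scale, log = TRUE))
}

lnorm_pars <- function(theta, sigma) {
  list(meanlog = log(theta^2 / sqrt(theta^2 + sigma^2)),
       sdlog = sqrt(log1p(sigma^2 / theta^2)))
}

#' Log prior density of a parameter vector
#'
#' Joint log density of all model parameters under [fmc_prior()], including
#' the hierarchical lognormal layer for the `kappa_z` conditional on
#' `(theta, sigma)`. Returns `-Inf` outside the support (negative rates,
#' non-positive `theta`, `sigma` or `kappa`, offsets outside (0, 1)).
#'
#' @param pars numeric vector laid out as [fmc_param_names()].
#' @param S stem cell number the vector is dimensioned for.
#' @param prior an [fmc_prior()] object.
#' @return Single log density value.
#' @export
fmc_log_prior <- function(pars, S, prior = fmc_prior()) {
  S <- check_S(S)
  nz <- 2 * S + 1
  if (length(pars) != 7 + nz)
    stop("parameter vector has wrong length for S = ", S, call. = FALSE)
  pars <- unname(pars)
  lambda <- pars[1]; mu <- pars[2]; gamma <- pars[3]
  delta <- pars[4]; epsilon <- pars[5]; theta <- pars[6]; sigma <- pars[7]
  kappa <- pars[-(1:7)]
  if (theta <= 0 || sigma <= 0 || any(kappa <= 0)) return(-Inf)
  if (delta <= 0 || delta >= 1 || epsilon <= 0 || epsilon >= 1) return(-Inf)
  lp <- dhalfnorm_log(lambda, prior$lambda_scale) +
    dhalfnorm_log(mu, prior$mu_scale) +
    dhalfnorm_log(gamma, prior$gamma_scale) +
    dbeta(delta, prior$delta_shape[1], prior$delta_shape[2], log = TRUE) +
    dbeta(epsilon, prior$epsilon_shape[1], prior$epsilon_shape[2],
          log = TRUE) +
    dhalfnorm_log(theta, prior$theta_scale) +
    dhalfnorm_log(sigma, prior$sigma_scale)
  ln <- lnorm_pars(theta, sigma)
  lp + sum(stats::dlnorm(kappa, ln$meanlog, ln$sdlog, log = TRUE))
}

#' Map unit-cube draws through the prior quantile functions
#'
#' The nested sampler explores the unit hypercube; this transform maps a
#' cube point to model parameters via each prior's quantile function, with
#' the `kappa_z` coordinates transformed conditional on the `(theta, sigma)`
#' coordinates (the hierarchy flattened into the sampled vector).
#'
#' @param u numeric vector in `[0, 1]^(8 + 2S)`.
#' @inheritParams fmc_log_prior
#' @return Named parameter vector.
#' @export
fmc_prior_transform <- function(u, S, prior = fmc_prior()) {
  S <- check_S(S)
  nz <- 2 * S + 1
  if (length(u) != 7 + nz || any(u < 0) || any(u > 1))
    stop("u must lie in the unit cube of dimension ", 7 + nz, call. = FALSE)
  qhn <- function(p, scale) scale * qnorm(0.5 + 0.5 * p)
  theta <- qhn(u[6], prior$theta_scale)
  sigma <- qhn(u[7], prior$sigma_scale)
  ln <- lnorm_pars(theta, sigma)
  setNames(
    c(qhn(u[1], prior$lambda_scale),
      qhn(u[2], prior$mu_scale),
      qhn(u[3], prior$gamma_scale),
      qbeta(u[4], prior$delta_shape[1], prior$delta_shape[2]),
      qbeta(u[5], prior$epsilon_shape[1], prior$epsilon_shape[2]),
      theta, sigma,
      qlnorm(u[-(1:7)], ln$meanlog, ln$sdlog)),
    fmc_param_names(S))
}

#' Draw parameter vectors from the prior
#'
#' @param n number of draws.
#' @inheritParams fmc_log_prior
#' @param seed optional integer seed for reproducibility.
#' @return Matrix with `n` rows, columns [fmc_param_names()].
#' @export
fmc_sample_prior <- function(n, S, prior = fmc_prior(), seed = NULL) {
  S <- check_S(S)
  if (!is.null(seed)) set.seed(seed)
  nz <- 2 * S + 1
  rhn <- function(scale) abs(rnorm(n, 0, scale))
  theta <- rhn(prior$theta_scale)
  sigma <- rhn(prior$sigma_scale)
  ln <- lnorm_pars(theta, sigma)
  kappa <- matrix(rlnorm(n * nz, rep(ln$meanlog, nz), rep(ln$sdlog, nz)),
                  n, nz)
  out <- cbind(rhn(prior$lambda_scale), rhn(prior$mu_scale),
               rhn(prior$gamma_scale),
               rbeta(n, prior$delta_shape[1], prior$delta_shape[2]),
               rbeta(n, prior$epsilon_shape[1], prior$epsilon_shape[2]),
               theta, sigma, kappa)
  colnames(out) <- fmc_param_names(S)
  out
}
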