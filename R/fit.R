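#' Fit the fluctuating methylation clock model to one crypt
#'
#' The main entry point: given the fCpG beta values of a single crypt (or
#' gland) and the donor's age, infers the stem cell number `S`, the
#' replacement rate `lambda`, the (de)methylation rates `mu` and `gamma`,
#' and the array-noise parameters. Nested sampling ([fmc_nested()]) is run
#' once per candidate `S`; evidences are combined into `P(S | beta)` by
#' softmax of the log evidences, and a model-averaged posterior is drawn by
#' stratified resampling.
#'
#' @param beta numeric vector of fCpG beta values in `[0, 1]`; boundary
#'   values are clamped via [fmc_clamp_beta()].
#' @param age donor age in years (the model's elapsed time since the niche
#'   was founded).
#' @param S integer vector of candidate stem cell numbers (default `3:20`,
#'   the conventional inference grid; restrict for speed).
#' @param prior an [fmc_prior()].
#' @param nlive,walks,dlogz nested sampler controls, see [fmc_nested()].
#' @param n_samples model-averaged posterior draws to keep.
#' @param seed master seed; per-S sampler seeds are derived from it
#'   deterministically.
#' @param verbose print per-S progress with timings.
#' @return An object of class `"fmc_fit"` with components `evidence`
#'   (data frame from [fmc_combine_evidence()]), `runs` (per-S
#'   [fmc_nested()] results), `posterior` (model-averaged draws), `beta`,
#'   `age`, `prior`, `seed`, and `call`.
#' @examples
#' \donttest{
#' crypt <- fmc_simulate_crypt(S = 5, lambda = 1, mu = 0.05, gamma = 0.05,
#'                             age = 60, n_loci = 300, seed = 1)
#' fit <- fmc_fit(crypt$beta, age = 60, S = 4:6, nlive = 100, seed = 1)
#' summary(fit)
#' }
#' @export
fmc_fit <- function(beta, age, S = 3:20, prior = fmc_prior(), nlive = 400,
                    walks = 25, dlogz = 0.05, n_samples = 4000L,
                    seed = NULL, verbose = FALSE) {
  cl <- match.call()
  S <- sort(unique(vapply(S, check_S, integer(1))))
  beta <- fmc_clamp_beta(beta)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(S) + 1L)
  runs <- vector("list", length(S))
  for (i in seq_along(S)) {
    t0 <- proc.time()[["elapsed"]]
    runs[[i]] <- fmc_nested(beta, age, S[i], prior = prior, nlive = nlive,
                            walks = walks, dlogz = dlogz, seed = sub_seeds[i])
    if (verbose)
      message(sprintf("S = %d: logZ = %.2f +/- %.2f (%d iter, %.1f s)",
                      S[i], runs[[i]]$logz, runs[[i]]$logzerr,
                      runs[[i]]$niter,
                      proc.time()[["elapsed"]] - t0))
  }
  set.seed(sub_seeds[length(S) + 1L])
  evidence <- fmc_combine_evidence(runs)
  posterior <- fmc_combined_posterior(runs, evidence, n = n_samples)
  structure(
    list(evidence = evidence, runs = runs, posterior = posterior,
         beta = beta, age = age, prior = prior, nlive = nlive,
         walks = walks, seed = seed, call = cl),
    class = "fmc_fit")
}

#' @exportS3Method print fmc_fit
print.fmc_fit <- function(x, ...) {
  cat("Fluctuating methylation clock fit\n")
  cat(sprintf("  %d fCpG loci, donor age %.4g years\n",
              length(x$beta), x$age))
  mode_S <- x$evidence$S[which.max(x$evidence$prob)]
  cat(sprintf("  Posterior-modal stem cell number: S = %d (P = %.3f)\n",
              mode_S, max(x$evidence$prob)))
  cm <- coef(x)
  cat(sprintf("  Posterior means: lambda = %.3g, mu = %.3g, gamma = %.3g\n",
              cm[["lambda"]], cm[["mu"]], cm[["gamma"]]))
  invisible(x)
}

#' @export
coef.fmc_fit <- function(object, ...) {
  p <- object$posterior
  keep <- c("S", "lambda", "mu", "gamma", "delta", "epsilon")
  colMeans(p[, keep, drop = FALSE])
}

#' Posterior summary of a fluctuating methylation clock fit
#'
#' @param object an [fmc_fit()] result.
#' @param probs credible interval probabilities (default 95% equal-tailed).
#' @param ... unused.
#' @return A list of class `"summary.fmc_fit"` with the `P(S | beta)` table
#'   and a parameter table of posterior means and credible intervals.
#' @exportS3Method summary fmc_fit
summary.fmc_fit <- function(object, probs = c(0.025, 0.975), ...) {
  p <- object$posterior
  pars <- c("S", "lambda", "mu", "gamma", "delta", "epsilon",
            "theta", "sigma")
  tab <- t(vapply(pars, function(nm) {
    v <- p[, nm]
    c(mean = mean(v, na.rm = TRUE),
      quantile(v, probs, na.rm = TRUE, names = FALSE))
  }, numeric(1 + length(probs))))
  colnames(tab) <- c("mean", paste0("q", format(probs)))
  out <- list(evidence = object$evidence, params = tab,
              n_loci = length(object$beta), age = object$age)
  class(out) <- "summary.fmc_fit"
  out
}

#' @exportS3Method print summary.fmc_fit
print.summary.fmc_fit <- function(x, ...) {
  cat(sprintf("fCpG loci: %d   donor age: %.4g years\n\n",
              x$n_loci, x$age))
  cat("Posterior over stem cell number:\n")
  ev <- x$evidence
  print(data.frame(S = ev$S, prob = round(ev$prob, 4),
                   prob_sd = round(ev$prob_sd, 4),
                   logZ = round(ev$logz, 2),
                   logZ_err = round(ev$logzerr, 2)),
        row.names = FALSE)
  cat("\nModel-averaged posterior (means and equal-tailed intervals):\n")
  print(round(x$params, 5))
  invisible(x)
}

#' Posterior predictive density of a fit
#'
#' @param object an [fmc_fit()] result.
#' @param newdata beta grid at which to evaluate the predictive density
#'   (defaults to 200 points spanning (0, 1)).
#' @param ndraw posterior draws to average over.
#' @param ... unused.
#' @return Data frame with columns `beta` and `density`.
#' @export
predict.fmc_fit <- function(object, newdata = seq(0.001, 0.999,
                                                  length.out = 200),
                            ndraw = 200L, ...) {
  p <- object$posterior
  idx <- sample.int(nrow(p), min(ndraw, nrow(p)))
  data.frame(beta = newdata,
             density = fmc_predictive_density(p[idx, , drop = FALSE],
                                              object$age, grid = newdata))
}

#' Plot a fitted crypt: beta histogram with posterior predictive overlay
#'
#' @param x an [fmc_fit()] result.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.fmc_fit <- function(x, breaks = seq(0, 1, by = 0.02), ...) {
  hist(x$beta, breaks = breaks, freq = FALSE, xlab = "beta value",
       main = "fCpG methylation with posterior predictive density", ...)
  pd <- predict(x)
  lines(pd$beta, pd$density, col = "salmon", lwd = 2)
  invisible(x)
}

#' Simulate replicate crypts from the posterior of a fit
#'
#' Draws parameter vectors from the model-averaged posterior and generates
#' synthetic crypts with the matching Gillespie simulator and noise model.
#'
#' @param object an [fmc_fit()] result.
#' @param nsim number of replicate crypts.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of `nsim` beta vectors (each of the fitted crypt's size).
#' @export
simulate.fmc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$posterior
  idx <- sample.int(nrow(p), nsim, replace = TRUE)
  lapply(idx, function(j) {
    S <- as.integer(p[j, "S"])
    kap <- p[j, paste0("kappa_", 0:(2 * S))]
    crypt <- fmc_simulate_crypt(
      S = S, lambda = p[j, "lambda"], mu = p[j, "mu"], gamma = p[j, "gamma"],
      age = object$age, n_loci = length(object$beta),
      delta = p[j, "delta"], epsilon = p[j, "epsilon"], kappa = kap)
    crypt$beta
  })
}

#' Convergence check across independently seeded fits
#'
#' Runs [fmc_rhat()] on equal-weight posterior draws from several
#' independently seeded [fmc_fit()] (or [fmc_nested()]) runs of the same
#' data and reports the rank-normalized split R-hat per parameter.
#'
#' @param fits list of >= 2 `fmc_fit` objects (or `fmc_nested` results with
#'   equal `S`).
#' @param pars parameters to check.
#' @param ndraw equal-weight draws per run.
#' @return Named vector of R-hat values with attribute `converged`
#'   (all < 1.1).
#' @export
fmc_convergence <- function(fits, pars = c("lambda", "mu", "gamma", "delta",
                                           "epsilon", "theta", "sigma"),
                            ndraw = 1000L) {
  if (length(fits) < 2L) stop("need >= 2 independent runs", call. = FALSE)
  draws <- array(NA_real_, c(ndraw, length(fits), length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    m <- if (inherits(f, "fmc_fit")) {
      f$posterior[sample.int(nrow(f$posterior), ndraw, replace = TRUE), ,
                  drop = FALSE]
    } else {
      fmc_resample(f, ndraw)
    }
    draws[, i, ] <- m[, pars]
  }
  rh <- fmc_rhat(draws)
  attr(rh, "converged") <- all(rh < 1.1)
  rh
}

#' Mean conditional fixation time of a stem lineage
#'
#' Expected time for a single labelled stem cell lineage to sweep the whole
#' niche (monoclonal conversion), conditional on it doing so. The labelled
#' count follows a birth-death chain with symmetric up/down rates
#' `lambda * n * (S - n) / (S - 1)`; the `"chain"` method solves the
#' first-step-analysis linear system for the Doob h-transformed
#' (fixation-conditioned) chain, the `"simulation"` method averages
#' Gillespie runs that reach fixation. Both scale as `1 / lambda`.
#'
#' @param S stem cell number (>= 2).
#' @param lambda replacement rate per stem cell per year (> 0).
#' @param method `"chain"` (exact) or `"simulation"`.
#' @param nreps total simulation runs (those hitting loss are discarded).
#' @param seed optional seed for the simulation method.
#' @return For `"chain"`, the mean conditional fixation time in years; for
#'   `"simulation"`, the same with attributes `se` (Monte-Carlo standard
#'   error) and `n_fixed`.
#' @examples
#' fmc_fixation_time(5, 1)
#' @export
fmc_fixation_time <- function(S, lambda, method = c("chain", "simulation"),
                              nreps = 10000L, seed = NULL) {
  S <- check_S(S)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  method <- match.arg(method)
  rate <- function(n) lambda * n * (S - n) / (S - 1)
  if (method == "chain") {
    # condition on fixation via h(n) = n / S, then solve
    # tau_n = 1/R_n + (up_n tau_{n+1} + down_n tau_{n-1}) / R_n
    n <- 1:(S - 1)
    up <- rate(n) * (n + 1) / n      # q+ * h(n+1)/h(n)
    down <- rate(n) * (n - 1) / n    # q- * h(n-1)/h(n)
    R <- up + down
    A <- diag(R, S - 1, S - 1)
    for (i in seq_len(S - 1)) {
      if (i < S - 1) A[i, i + 1] <- -up[i]
      if (i > 1) A[i, i - 1] <- -down[i]
    }
    tau <- solve(A, rep(1, S - 1))
    return(tau[1])
  }
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  for (r in seq_len(nreps)) {
    n <- 1L; t <- 0
    while (n > 0L && n < S) {
      R <- 2 * rate(n)
      t <- t + rexp(1, R)
      n <- n + sample(c(1L, -1L), 1L)
    }
    if (n == S) times <- c(times, t)
  }
  if (!length(times)) stop("no run reached fixation; increase nreps")
  structure(mean(times), se = sd(times) / sqrt(length(times)),
            n_fixed = length(times))
}
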