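logaddexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Nested sampling for one candidate stem cell number
#'
#' Static nested sampling of the crypt model posterior at a fixed `S`,
#' yielding the Bayesian evidence (marginal likelihood) together with
#' weighted posterior samples. New live points are generated from existing
#' live points by a likelihood-constrained random walk in the unit cube
#' ('rwalk'), with the step scale adapted towards 50% acceptance. The
#' posterior over `S` is multimodal (each `S` has its own mode, correlated
#' with `lambda`), which is why evidence is computed per `S` and combined
#' afterwards rather than sampling `S` jointly.
#'
#' @param beta vector of fCpG beta values strictly inside (0, 1) (use
#'   [fmc_clamp_beta()] first if needed).
#' @param age donor age in years.
#' @param S candidate stem cell number (>= 2; the inference grid
#'   conventionally starts at 3).
#' @param prior an [fmc_prior()].
#' @param nlive number of live points.
#' @param walks random-walk steps per replacement.
#' @param dlogz stopping tolerance on the estimated remaining log evidence.
#' @param max_iter safety cap on iterations.
#' @param seed integer seed; runs are reproducible given the seed.
#' @param loglik optional R function `function(pars) -> log likelihood`
#'   overriding the compiled crypt likelihood (used for validation, e.g. a
#'   constant likelihood must return logZ = 0 for a normalised prior).
#' @return An object of class `"fmc_nested"`: list with `S`, `logz`,
#'   `logzerr`, `samples` (matrix of parameter draws), `logwt` (log
#'   importance weights, normalised to `logz`), `logl`, `niter`, `ncall`,
#'   `nlive`, `seed`.
#' @export
fmc_nested <- function(beta, age, S, prior = fmc_prior(), nlive = 400,
                       walks = 25, dlogz = 0.05, max_iter = 200000L,
                       seed = NULL, loglik = NULL) {
  S <- check_S(S)
  if (!is.null(seed)) set.seed(seed)
  d <- 8L + 2L * S
  pc <- prior_config_vector(prior)
  lb <- log(beta); l1mb <- log1p(-beta)
  ncall <- 0L
  eval_u <- if (is.null(loglik)) {
    function(u) cpp_loglik_u(u, lb, l1mb, age, S, pc)
  } else {
    function(u) loglik(fmc_prior_transform(u, S, prior))
  }
  # proposals are whitened by the live-point covariance so the walk mixes
  # across dimensions whose posterior widths differ by orders of magnitude
  chol_cov <- function(u) t(chol(stats::cov(u) + diag(1e-10, ncol(u))))
  walk_fn <- if (is.null(loglik)) {
    function(u0, lstar, scale, L) {
      res <- cpp_rwalk(u0, lstar, scale, walks, L, lb, l1mb, age, S, pc)
      ncall <<- ncall + walks
      res
    }
  } else {
    function(u0, lstar, scale, L) {
      u <- u0; ll_cur <- -Inf; nacc <- 0L
      for (w in seq_len(walks)) {
        v <- abs(u + scale * as.numeric(L %*% rnorm(d))) %% 2
        v <- ifelse(v > 1, 2 - v, v)
        ll <- eval_u(v); ncall <<- ncall + 1L
        if (ll >= lstar) { u <- v; ll_cur <- ll; nacc <- nacc + 1L }
      }
      list(u = u, logl = ll_cur, naccept = nacc)
    }
  }

  u_live <- matrix(runif(nlive * d), nlive, d)
  logl_live <- apply(u_live, 1, eval_u)
  ncall <- ncall + nlive

  cap <- 4096L
  dead_u <- matrix(NA_real_, cap, d)
  dead_logl <- numeric(cap)
  dead_logwt <- numeric(cap)
  ndead <- 0L
  grow <- function() {
    cap2 <- 2L * cap
    du <- matrix(NA_real_, cap2, d); du[1:cap, ] <- dead_u
    dead_u <<- du
    dead_logl <<- c(dead_logl, numeric(cap))
    dead_logwt <<- c(dead_logwt, numeric(cap))
    cap <<- cap2
  }

  logz <- -Inf
  scale <- 1
  Lprop <- chol_cov(u_live)
  refresh <- max(50L, nlive %/% 4L)
  dlv <- log1p(-exp(-1 / nlive))  # log(X_{i-1} - X_i) - logX_{i-1}
  it <- 0L
  repeat {
    it <- it + 1L
    worst <- which.min(logl_live)
    logl_star <- logl_live[worst]
    logx_prev <- -(it - 1) / nlive
    logwt <- logx_prev + dlv + logl_star
    logz <- logaddexp(logz, logwt)
    if (ndead + 1L > cap) grow()
    ndead <- ndead + 1L
    dead_u[ndead, ] <- u_live[worst, ]
    dead_logl[ndead] <- logl_star
    dead_logwt[ndead] <- logx_prev + dlv

    if (it %% refresh == 0L) Lprop <- chol_cov(u_live)
    # replace the worst point: walk from a random surviving live point
    for (try in 1:50) {
      start <- sample.int(nlive, 1L)
      if (nlive > 1L && start == worst)
        start <- if (worst == nlive) 1L else worst + 1L
      step <- walk_fn(u_live[start, ], logl_star, scale, Lprop)
      facc <- step$naccept / walks
      scale <- scale * exp((facc - 0.5) / d)
      scale <- min(max(scale, 1e-4), 10)
      if (step$naccept > 0) break
    }
    if (step$naccept == 0)
      stop("nested sampler stalled: no live-point improvement after ",
           "50 restarts at iteration ", it, " (logz so far ",
           signif(logz, 6), ")", call. = FALSE)
    u_live[worst, ] <- step$u
    logl_live[worst] <- step$logl

    logz_remain <- logsumexp(logl_live) - log(nlive) - it / nlive
    if (logaddexp(logz, logz_remain) - logz < dlogz) break
    if (it >= max_iter) {
      warning("nested sampling hit max_iter before reaching dlogz")
      break
    }
  }

  # fold in the surviving live points, each with volume X_final / nlive
  logx_final <- -it / nlive
  need <- ndead + nlive
  while (need > cap) grow()
  ord <- order(logl_live)
  for (j in seq_len(nlive)) {
    ndead <- ndead + 1L
    dead_u[ndead, ] <- u_live[ord[j], ]
    dead_logl[ndead] <- logl_live[ord[j]]
    dead_logwt[ndead] <- logx_final - log(nlive)
    logz <- logaddexp(logz, logx_final - log(nlive) + logl_live[ord[j]])
  }

  dead_u <- dead_u[seq_len(ndead), , drop = FALSE]
  dead_logl <- dead_logl[seq_len(ndead)]
  dead_logwt <- dead_logwt[seq_len(ndead)]

  # information and classic evidence error estimate
  logp <- dead_logwt + dead_logl - logz
  p <- exp(logp)
  H <- sum(p * dead_logl) - logz
  logzerr <- sqrt(max(H, 0) / nlive)

  samples <- t(apply(dead_u, 1, fmc_prior_transform, S = S, prior = prior))
  colnames(samples) <- fmc_param_names(S)
  structure(
    list(S = S, logz = logz, logzerr = max(logzerr, 1e-10),
         samples = samples, logwt = dead_logwt + dead_logl - logz,
         logl = dead_logl, niter = it, ncall = ncall, nlive = nlive,
         walks = walks, seed = seed, H = H),
    class = "fmc_nested")
}

#' Equal-weight posterior draws from a nested sampling run
#'
#' @param ns an [fmc_nested()] result.
#' @param n number of draws.
#' @return Matrix of `n` parameter draws (importance resampled).
#' @export
fmc_resample <- function(ns, n = 1000L) {
  w <- exp(ns$logwt - logsumexp(ns$logwt))
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  ns$samples[idx, , drop = FALSE]
}

#' Combine per-S evidences into a posterior over the stem cell number
#'
#' `P(S | beta) = Z(S) / sum_j Z(S_j)`: the softmax of the per-S log
#' evidences. Uncertainty is propagated by resampling each log evidence
#' from Normal(logz, logzerr) and recomputing the softmax, reporting the
#' 1-s.d. band of the resampled probabilities.
#'
#' @param results list of [fmc_nested()] results with distinct `S`.
#' @param ndraw Monte-Carlo draws for the error band.
#' @return Data frame with columns `S`, `prob`, `prob_sd`, `logz`, `logzerr`.
#' @export
fmc_combine_evidence <- function(results, ndraw = 1000L) {
  S <- vapply(results, `[[`, integer(1), "S")
  if (anyDuplicated(S)) stop("duplicate S values in results", call. = FALSE)
  logz <- vapply(results, `[[`, numeric(1), "logz")
  logzerr <- vapply(results, `[[`, numeric(1), "logzerr")
  prob <- exp(logz - logsumexp(logz))
  draws <- matrix(rnorm(ndraw * length(S), rep(logz, each = ndraw),
                        rep(logzerr, each = ndraw)), ndraw, length(S))
  pdraws <- exp(draws - apply(draws, 1, logsumexp))
  data.frame(S = S, prob = prob, prob_sd = apply(pdraws, 2, sd),
             logz = logz, logzerr = logzerr)
}

#' Model-averaged posterior samples across stem cell numbers
#'
#' Stratified resampling: each draw first picks `S` from `P(S | beta)`,
#' then an importance-resampled parameter draw from that S's weighted
#' nested samples. Parameters absent for a given `S` (higher `kappa_z`) are
#' `NA` in the returned matrix.
#'
#' @param results list of [fmc_nested()] results.
#' @param evidence optional result of [fmc_combine_evidence()].
#' @param n number of draws.
#' @return Matrix with columns `S`, shared parameters and `kappa_z` up to
#'   the largest `S`.
#' @export
fmc_combined_posterior <- function(results, evidence = NULL, n = 4000L) {
  if (is.null(evidence)) evidence <- fmc_combine_evidence(results)
  Smax <- max(evidence$S)
  cols <- c("S", fmc_param_names(Smax))
  ns_draw <- as.vector(stats::rmultinom(1, n, evidence$prob))
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  row <- 1L
  for (j in seq_along(results)) {
    if (ns_draw[j] == 0) next
    sm <- fmc_resample(results[[j]], ns_draw[j])
    idx <- row:(row + ns_draw[j] - 1L)
    out[idx, "S"] <- results[[j]]$S
    out[idx, colnames(sm)] <- sm
    row <- row + ns_draw[j]
  }
  out[sample.int(n), , drop = FALSE]
}

#' Rank-normalized split potential scale reduction statistic
#'
#' Computes the rank-normalized split R-hat convergence diagnostic: all
#' draws are replaced by normal scores of their pooled ranks, each chain is
#' split in half, and the classic between/within-chain variance ratio is
#' computed on the normalised halves. Values near 1 indicate agreement
#' between independent runs; `>= 1.1` is the conventional failure
#' threshold.
#'
#' @param draws matrix (iterations x chains) of draws of one parameter, or
#'   a 3-d array (iterations x chains x parameters).
#' @return R-hat value(s); a named vector for array input.
#' @export
fmc_rhat <- function(draws) {
  if (length(dim(draws)) == 3L) {
    out <- apply(draws, 3, fmc_rhat)
    return(out)
  }
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (m < 2L) stop("need draws from >= 2 independent runs", call. = FALSE)
  if (n < 4L) stop("need >= 4 draws per run", call. = FALSE)
  half <- floor(n / 2)
  split <- cbind(draws[1:half, , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  r <- matrix(rank(split, ties.method = "average"), nrow(split), ncol(split))
  z <- qnorm((r - 3 / 8) / (length(split) + 1 / 4))
  nn <- nrow(z)
  means <- colMeans(z)
  B <- nn * var(means)
  W <- mean(apply(z, 2, var))
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
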