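#' Select a blood fCpG panel by cohort mean methylation
#'
#' In whole blood the bulk averages over very many stem lineages, so
#' fluctuating loci sit near 50% methylation in every healthy sample. The
#' blood panel is simply all loci whose cohort mean beta lies in
#' `[0.40, 0.60]` (inclusive).
#'
#' @param beta loci x samples matrix with locus rownames.
#' @param mean_range inclusive cohort-mean window.
#' @return Character vector of panel locus ids.
#' @export
fmc_blood_panel <- function(beta, mean_range = c(0.4, 0.6)) {
  mb <- rowMeans(beta)
  rownames(beta)[mb >= mean_range[1] & mb <= mean_range[2]]
}

#' Variance of a sample's fCpG beta values
#'
#' The population variance (divisor `n`) of the beta values across panel
#' loci for one sample: the scalar summary that rises with clonal
#' expansion in blood.
#'
#' @param beta numeric vector of beta values over the panel loci.
#' @return Single variance value.
#' @export
fmc_sample_variance <- function(beta) {
  beta <- beta[is.finite(beta)]
  if (!length(beta)) stop("no finite beta values", call. = FALSE)
  mean((beta - mean(beta))^2)
}

#' Trimodality ('W shape') summary of a beta distribution
#'
#' Heuristic summary of how W-shaped a beta histogram is: the fractions of
#' loci below 0.2, between 0.2 and 0.8, and above 0.8, plus the number of
#' local maxima of the binned histogram. A clonal population with
#' just-right fluctuation rates shows three peaks (near 0, 1/2 and 1) and a
#' large outer fraction; a polyclonal population concentrates in the centre.
#'
#' @param beta numeric vector of beta values.
#' @param bin_width histogram bin width for peak counting.
#' @return List with `frac_low`, `frac_mid`, `frac_high`, `outer_frac`
#'   (`frac_low + frac_high`) and `n_peaks`.
#' @export
fmc_w_shape <- function(beta, bin_width = 0.05) {
  stopifnot(length(beta) > 0)
  frac_low <- mean(beta < 0.2)
  frac_high <- mean(beta > 0.8)
  h <- hist(beta, breaks = seq(0, 1, by = bin_width), plot = FALSE)
  # 3-bin moving average damps sampling wiggles before peak finding; a peak
  # is a maximal run of equal smoothed counts strictly above both
  # neighbouring runs (plateaus from smoothed spikes count once)
  cnt <- h$counts
  sm <- (c(cnt[1], cnt[-length(cnt)]) + cnt + c(cnt[-1], cnt[length(cnt)])) / 3
  r <- rle(sm)
  v <- c(-1, r$values, -1)
  peaks <- sum(vapply(seq_along(r$values), function(j) {
    v[j + 1] > v[j] && v[j + 1] > v[j + 2] &&
      r$values[j] > 0.02 * length(beta)
  }, logical(1)))
  list(frac_low = frac_low, frac_mid = 1 - frac_low - frac_high,
       frac_high = frac_high, outer_frac = frac_low + frac_high,
       n_peaks = peaks)
}

flip_probs <- function(mu, gamma, dt) {
  # two-state per-allele chain: P(meth at dt | start state)
  tot <- mu + gamma
  if (tot == 0) return(c(p01 = 0, p11 = 1))
  pstat <- mu / tot
  decay <- exp(-tot * dt)
  c(p01 = pstat * (1 - decay), p11 = pstat + (1 - pstat) * decay)
}

#' Simulate hematopoiesis with an expanding clone
#'
#' A simple model of how fluctuating methylation detects clonal
#' hematopoiesis. The background marrow is a large pool of independent
#' stem lineages, each a diploid cell whose per-locus allele count in
#' `{0, 1, 2}` flips allele-wise at rates `mu` (methylation) and `gamma`
#' (demethylation); the polyclonal bulk beta of every locus therefore sits
#' near 0.5. At `clone_start` years one lineage founds a clone whose blood
#' fraction grows logistically to `clone_final_fraction` at rate
#' `clone_growth_rate`; within the clone, fluctuations desynchronise from
#' the founder state at the same flip rates, so the clone's bulk beta per
#' locus relaxes from the founder's `{0, 1/2, 1}` value towards 0.5. The
#' observed bulk mixes clone and background by the clone fraction.
#'
#' @param n_lineages background stem lineages simulated (the real marrow
#'   has many more; the background variance scales as 1/n_lineages).
#' @param n_loci fCpG loci.
#' @param mu,gamma per-allele flip rates per year.
#' @param clone_start year the clone is founded.
#' @param clone_growth_rate logistic growth rate (per year) of the clone's
#'   blood fraction.
#' @param clone_final_fraction carrying capacity of the clone fraction in
#'   `[0, 1]`; 0 disables the clone.
#' @param times observation times in years.
#' @param initial_fraction clone fraction at founding.
#' @param seed optional seed.
#' @return List of class `"fmc_blood_sim"`: `times`, `beta` (matrix loci x
#'   times of bulk beta), `variance` (per time), `clone_fraction` (per
#'   time), and the configuration.
#' @export
fmc_simulate_hematopoiesis <- function(n_lineages = 2000, n_loci = 2000,
                                       mu = 0.05, gamma = 0.05,
                                       clone_start = 40,
                                       clone_growth_rate = 2,
                                       clone_final_fraction = 0,
                                       times = seq(0, 70, by = 5),
                                       initial_fraction = 1e-4,
                                       seed = NULL) {
  stopifnot(clone_final_fraction >= 0, clone_final_fraction <= 1,
            mu >= 0, gamma >= 0, all(diff(times) > 0))
  if (!is.null(seed)) set.seed(seed)
  # allele states: two loci x lineages binary matrices
  a1 <- matrix(rbinom(n_loci * n_lineages, 1, 0.5), n_loci, n_lineages)
  a2 <- matrix(rbinom(n_loci * n_lineages, 1, 0.5), n_loci, n_lineages)
  step <- function(m, dt) {
    pr <- flip_probs(mu, gamma, dt)
    p <- ifelse(m == 1, pr["p11"], pr["p01"])
    matrix(rbinom(length(m), 1, p), nrow(m), ncol(m))
  }
  clone_founder <- NULL
  founder_time <- NA_real_
  clone_frac <- function(t) {
    if (clone_final_fraction == 0 || t <= clone_start) return(0)
    f0 <- initial_fraction * clone_final_fraction
    odds0 <- f0 / (clone_final_fraction - f0)
    f <- clone_final_fraction /
      (1 + exp(-clone_growth_rate * (t - clone_start)) / odds0)
    min(f, clone_final_fraction)
  }
  tcur <- 0
  beta_mat <- matrix(NA_real_, n_loci, length(times))
  vars <- numeric(length(times))
  fr <- numeric(length(times))
  # event grid: observation times plus the clone founding instant
  grid <- sort(unique(c(times, clone_start)))
  for (tg in grid) {
    dt <- tg - tcur
    if (dt > 0) { a1 <- step(a1, dt); a2 <- step(a2, dt) }
    tcur <- tg
    if (clone_final_fraction > 0 && tg == clone_start) {
      clone_founder <- a1[, 1] + a2[, 1]  # allele count of lineage 1
      founder_time <- tg
    }
    if (tg %in% times) {
      i <- match(tg, times)
      bg <- (rowMeans(a1) + rowMeans(a2)) / 2
      f <- clone_frac(tg)
      if (f > 0) {
        pr <- flip_probs(mu, gamma, tg - founder_time)
        clone_beta <- (clone_founder * pr["p11"] +
                         (2 - clone_founder) * pr["p01"]) / 2
        b <- f * clone_beta + (1 - f) * bg
      } else {
        b <- bg
      }
      beta_mat[, i] <- b
      vars[i] <- fmc_sample_variance(b)
      fr[i] <- f
    }
  }
  structure(list(times = times, beta = beta_mat, variance = vars,
                 clone_fraction = fr,
                 config = list(n_lineages = n_lineages, n_loci = n_loci,
                               mu = mu, gamma = gamma,
                               clone_start = clone_start,
                               clone_growth_rate = clone_growth_rate,
                               clone_final_fraction = clone_final_fraction,
                               initial_fraction = initial_fraction,
                               seed = seed)),
            class = "fmc_blood_sim")
}

#' @exportS3Method print fmc_blood_sim
print.fmc_blood_sim <- function(x, ...) {
  cat(sprintf(
    "Hematopoiesis simulation: %d lineages, %d loci, clone fraction -> %.2f\n",
    x$config$n_lineages, x$config$n_loci, x$config$clone_final_fraction))
  print(data.frame(time = x$times, clone_fraction = round(x$clone_fraction, 4),
                   variance = signif(x$variance, 4)), row.names = FALSE)
  invisible(x)
}
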