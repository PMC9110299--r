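#' Enumerate the state space of the stem cell niche
#'
#' The methylation state of one fCpG locus across a well-mixed niche of `S`
#' stem cells is fully described by the pair `(k, m)`: `k` cells carry exactly
#' one methylated allele (heterozygous) and `m` cells carry two (homozygous).
#' The remaining `S - k - m` cells are homozygously unmethylated. All pairs
#' with `0 <= k + m <= S` are admitted, giving `(S + 1) * (S + 2) / 2` states.
#'
#' States are ordered lexicographically in `(m, k)`; the ordering is fixed so
#' that generator matrices and probability vectors have a reproducible layout.
#'
#' @param S integer number of stem cells in the niche, at least 2 (the
#'   replacement terms carry a factor `lambda / (S - 1)`).
#' @return An object of class `"fmc_states"`: a list with elements `S`,
#'   `k` and `m` (integer vectors over states), `n_states`, and `z = k + 2m`
#'   (number of methylated alleles out of `2S`).
#' @examples
#' st <- fmc_states(5)
#' st$n_states  # 21
#' @export
fmc_states <- function(S) {
  S <- check_S(S)
  m <- unlist(lapply(0:S, function(mm) rep(mm, S - mm + 1L)))
  k <- unlist(lapply(0:S, function(mm) 0:(S - mm)))
  structure(
    list(S = S, k = as.integer(k), m = as.integer(m),
         n_states = as.integer((S + 1L) * (S + 2L) / 2L),
         z = as.integer(k + 2L * m)),
    class = "fmc_states")
}

check_S <- function(S) {
  if (length(S) != 1L || !is.finite(S) || S != round(S) || S < 2)
    stop("S must be a single integer >= 2", call. = FALSE)
  as.integer(S)
}

state_index <- function(states, k, m) {
  idx <- match(paste(k, m), paste(states$k, states$m))
  if (anyNA(idx)) stop("invalid (k, m) state for S = ", states$S, call. = FALSE)
  idx
}

#' Master-equation transition rate between two niche states
#'
#' Rate (per year) at which a niche of `S` stem cells jumps from state
#' `src = (k, m)` to `dst = (k', m')`. Six neighbour classes have non-zero
#' rates, combining stem cell replacement (each ordered pair of distinct
#' cells at rate `lambda / (S - 1)`, the replaced cell adopting the
#' replacer's epigenotype) with per-allele methylation (`mu`) and
#' demethylation (`gamma`):
#'
#' * `(k, m) -> (k+1, m)`: `(S-k-m) * (k * lambda/(S-1) + 2*mu)`
#' * `(k, m) -> (k-1, m)`: `k * ((S-k-m) * lambda/(S-1) + gamma)`
#' * `(k, m) -> (k, m+1)`: `m * (S-k-m) * lambda/(S-1)`
#' * `(k, m) -> (k, m-1)`: `m * (S-k-m) * lambda/(S-1)`
#' * `(k, m) -> (k-1, m+1)`: `k * (m * lambda/(S-1) + mu)`
#' * `(k, m) -> (k+1, m-1)`: `m * (k * lambda/(S-1) + 2*gamma)`
#'
#' All other transitions have rate 0.
#'
#' @param src,dst length-2 integer vectors `c(k, m)`.
#' @param S stem cell number (>= 2).
#' @param lambda replacement rate per stem cell per year.
#' @param mu methylation rate per unmethylated allele per year.
#' @param gamma demethylation rate per methylated allele per year.
#' @return A single non-negative rate (per year).
#' @examples
#' fmc_transition_rate(c(3, 1), c(3, 2), S = 5, lambda = 1, mu = 0, gamma = 0)
#' # 0.25: of the S*(S-1) = 20 ordered replacement pairs only one creates (3,2)
#' @export
fmc_transition_rate <- function(src, dst, S, lambda, mu, gamma) {
  S <- check_S(S)
  check_rates(lambda, mu, gamma)
  valid <- function(s) length(s) == 2L && all(s >= 0) && sum(s) <= S &&
    all(s == round(s))
  if (!valid(src) || !valid(dst))
    stop("states must be (k, m) with 0 <= k + m <= S", call. = FALSE)
  if (all(src == dst))
    stop("src and dst must differ", call. = FALSE)
  k <- src[1]; m <- src[2]; w <- S - k - m
  dk <- dst[1] - k; dm <- dst[2] - m
  lam1 <- lambda / (S - 1)
  if (dk == 1 && dm == 0)  return(w * (k * lam1 + 2 * mu))
  if (dk == -1 && dm == 0) return(k * (w * lam1 + gamma))
  if (dk == 0 && dm == 1)  return(m * w * lam1)
  if (dk == 0 && dm == -1) return(m * w * lam1)
  if (dk == -1 && dm == 1) return(k * (m * lam1 + mu))
  if (dk == 1 && dm == -1) return(m * (k * lam1 + 2 * gamma))
  0
}

check_rates <- function(lambda, mu, gamma) {
  r <- c(lambda, mu, gamma)
  if (length(r) != 3L || !all(is.finite(r)) || any(r < 0))
    stop("lambda, mu, gamma must be single non-negative numbers",
         call. = FALSE)
  invisible(NULL)
}

#' Generator matrix of the niche master equation
#'
#' Builds the transition-rate matrix `T` such that the state probability
#' vector evolves as `dP/dt = T P`. Off-diagonal entries `T[j, i]` are the
#' rates from state `i` to state `j` (see [fmc_transition_rate()]); each
#' diagonal entry is minus the total outflow from its state, so every column
#' sums to zero (probability conservation).
#'
#' @inheritParams fmc_transition_rate
#' @param states optionally a precomputed [fmc_states()] object.
#' @return A dense `n_states x n_states` matrix with `"fmc_states"` attribute.
#' @export
fmc_generator <- function(S, lambda, mu, gamma, states = fmc_states(S)) {
  check_rates(lambda, mu, gamma)
  S <- states$S
  n <- states$n_states
  k <- states$k; m <- states$m; w <- S - k - m
  lam1 <- lambda / (S - 1)
  Tm <- matrix(0, n, n)
  idx <- function(kk, mm) {
    ok <- kk >= 0 & mm >= 0 & (kk + mm) <= S
    i <- rep(NA_integer_, length(kk))
    i[ok] <- match(paste(kk[ok], mm[ok]), paste(states$k, states$m))
    i
  }
  put <- function(dst, rate) {
    ok <- !is.na(dst) & rate > 0
    Tm[cbind(dst[ok], seq_len(n)[ok])] <<- rate[ok]
  }
  put(idx(k + 1L, m),      w * (k * lam1 + 2 * mu))
  put(idx(k - 1L, m),      k * (w * lam1 + gamma))
  put(idx(k, m + 1L),      m * w * lam1)
  put(idx(k, m - 1L),      m * w * lam1)
  put(idx(k - 1L, m + 1L), k * (m * lam1 + mu))
  put(idx(k + 1L, m - 1L), m * (k * lam1 + 2 * gamma))
  diag(Tm) <- 0
  diag(Tm) <- -colSums(Tm)
  attr(Tm, "fmc_states") <- states
  Tm
}

#' Initial niche state distribution at conception
#'
#' Early in embryogenesis parental methylation is erased and de novo
#' methylation remodels the genome, leaving a bimodal methylation landscape;
#' because the stem cells of a niche are initially clonal, each fCpG locus is
#' taken to start homozygously methylated across the whole niche with
#' probability 1/2, and homozygously unmethylated otherwise:
#' `P(k = 0, m = S) = P(k = 0, m = 0) = 0.5` at `t = 0`.
#'
#' @param S stem cell number (>= 2), or an [fmc_states()] object.
#' @return A probability vector over the state space.
#' @export
fmc_initial <- function(S) {
  states <- if (inherits(S, "fmc_states")) S else fmc_states(S)
  p <- numeric(states$n_states)
  p[states$k == 0L & states$m == 0L] <- 0.5
  p[states$k == 0L & states$m == states$S] <- 0.5
  p
}

#' Propagate a niche state distribution through time
#'
#' Solves the master equation by the matrix exponential,
#' `P(t) = expm(t T) P(0)`. Small negative round-off entries (above
#' `-1e-12`) are clipped to zero and the vector renormalised; larger
#' negative entries or non-finite values raise an error.
#'
#' @param p0 probability vector over the state space at time 0.
#' @param Tm generator matrix from [fmc_generator()].
#' @param t elapsed time in years (>= 0).
#' @return Probability vector at time `t`.
#' @export
fmc_propagate <- function(p0, Tm, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single non-negative number", call. = FALSE)
  if (length(p0) != nrow(Tm))
    stop("dimension mismatch between p0 and generator", call. = FALSE)
  if (t == 0) return(p0)
  p <- as.numeric(Matrix::expm(Matrix::Matrix(t * Tm, sparse = FALSE)) %*% p0)
  sanitize_prob(p)
}

sanitize_prob <- function(p, clip = 1e-12) {
  if (any(!is.finite(p)))
    stop("non-finite probabilities in propagated distribution", call. = FALSE)
  if (any(p < -clip))
    stop("propagation produced negative probabilities beyond round-off",
         call. = FALSE)
  p[p < 0] <- 0
  p / sum(p)
}

#' Marginal distribution of the niche methylated-allele count
#'
#' The array measures the bulk fraction of methylated alleles, not the
#' hidden per-cell states, so the `(k, m)` distribution is marginalised onto
#' `z = k + 2m`, the number of methylated allele copies among the `2S`
#' alleles of the niche.
#'
#' @param p probability vector over the state space.
#' @param states the matching [fmc_states()] object.
#' @return Numeric vector of length `2S + 1`; element `z + 1` is `P(z)`.
#' @export
fmc_marginal_z <- function(p, states) {
  if (length(p) != states$n_states)
    stop("dimension mismatch between p and state space", call. = FALSE)
  as.numeric(tapply(p, factor(states$z, levels = 0:(2L * states$S)), sum,
                    default = 0))
}

#' Distribution of the methylated-allele count at a given age
#'
#' Convenience composition: enumerate states, build the generator, propagate
#' the clonal initial condition to time `t` and marginalise onto
#' `z = k + 2m`.
#'
#' @inheritParams fmc_transition_rate
#' @param t age in years.
#' @return Numeric vector of length `2S + 1` with `P(z | lambda, mu, gamma; t)`.
#' @examples
#' pz <- fmc_zdist(S = 5, lambda = 1, mu = 0.05, gamma = 0.05, t = 60)
#' sum(pz)  # 1
#' @export
fmc_zdist <- function(S, lambda, mu, gamma, t) {
  states <- fmc_states(S)
  Tm <- fmc_generator(S, lambda, mu, gamma, states = states)
  fmc_marginal_z(fmc_propagate(fmc_initial(states), Tm, t), states)
}
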