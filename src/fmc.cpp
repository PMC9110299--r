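// Fast numerical core: master-equation propagation, beta-mixture likelihood,
// unit-cube random-walk steps for the nested sampler, and exact Gillespie
// simulation of the stem cell niche. Plain-R counterparts of the model code
// live in R/ and are cross-checked against these routines in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// State ordering is lexicographic in (m, k), matching fmc_states():
// index(k, m) = m*(S+1) - m*(m-1)/2 + k
static inline int state_index(int k, int m, int S) {
  return m * (S + 1) - (m * (m - 1)) / 2 + k;
}

static arma::mat build_generator(int S, double lambda, double mu, double gam) {
  const int n = (S + 1) * (S + 2) / 2;
  const double lam1 = lambda / (S - 1);
  arma::mat T(n, n, arma::fill::zeros);
  for (int m = 0; m <= S; ++m) {
    for (int k = 0; k <= S - m; ++k) {
      const int i = state_index(k, m, S);
      const int w = S - k - m;
      double out = 0.0;
      // (k, m) -> (k+1, m): unmethylated cell overwritten by het cell, or
      // one of its two alleles methylates
      if (k + 1 + m <= S) {
        double r = w * (k * lam1 + 2.0 * mu);
        T(state_index(k + 1, m, S), i) += r; out += r;
      }
      // (k, m) -> (k-1, m): het cell overwritten by unmethylated cell, or
      // its methylated allele demethylates
      if (k >= 1) {
        double r = k * (w * lam1 + gam);
        T(state_index(k - 1, m, S), i) += r; out += r;
      }
      // (k, m) -> (k, m+1): unmethylated cell overwritten by hom-meth cell
      if (k + m + 1 <= S) {
        double r = (double)m * w * lam1;
        T(state_index(k, m + 1, S), i) += r; out += r;
      }
      // (k, m) -> (k, m-1): hom-meth cell overwritten by unmethylated cell
      if (m >= 1) {
        double r = (double)m * w * lam1;
        T(state_index(k, m - 1, S), i) += r; out += r;
      }
      // (k, m) -> (k-1, m+1): het cell overwritten by hom-meth cell, or
      // its free allele methylates
      if (k >= 1) {
        double r = k * (m * lam1 + mu);
        T(state_index(k - 1, m + 1, S), i) += r; out += r;
      }
      // (k, m) -> (k+1, m-1): hom-meth cell overwritten by het cell, or
      // one of its two alleles demethylates
      if (m >= 1) {
        double r = m * (k * lam1 + 2.0 * gam);
        T(state_index(k + 1, m - 1, S), i) += r; out += r;
      }
      T(i, i) = -out;
    }
  }
  return T;
}

// P(z | lambda, mu, gamma; t) for z = 0..2S, from the clonal 50/50 initial
// condition, via dense matrix exponentiation of the generator.
// [[Rcpp::export]]
arma::vec cpp_zdist(int S, double lambda, double mu, double gam, double t) {
  const int n = (S + 1) * (S + 2) / 2;
  arma::vec p0(n, arma::fill::zeros);
  p0(state_index(0, 0, S)) = 0.5;
  p0(state_index(0, S, S)) = 0.5;
  arma::vec p;
  if (t == 0.0) {
    p = p0;
  } else {
    arma::mat E = arma::expmat(t * build_generator(S, lambda, mu, gam));
    p = E * p0;
  }
  if (!p.is_finite()) stop("non-finite probabilities in matrix exponential");
  if (p.min() < -1e-12)
    stop("propagation produced negative probabilities beyond round-off");
  p.clamp(0.0, arma::datum::inf);
  p /= arma::accu(p);
  arma::vec pz(2 * S + 1, arma::fill::zeros);
  for (int m = 0; m <= S; ++m)
    for (int k = 0; k <= S - m; ++k)
      pz(k + 2 * m) += p(state_index(k, m, S));
  return pz;
}

// Log-likelihood of one crypt: sum_i log sum_z P(beta_i | z) P(z | .; age).
// logb / log1mb are log(beta) and log(1 - beta), precomputed once per crypt.
// pars = (lambda, mu, gamma, delta, epsilon, theta, sigma, kappa_0..kappa_2S).
// [[Rcpp::export]]
double cpp_loglik(const arma::vec& logb, const arma::vec& log1mb,
                  double age, int S, const arma::vec& pars) {
  const int nz = 2 * S + 1;
  if ((int)pars.n_elem != 7 + nz) stop("parameter vector has wrong length");
  const double lambda = pars(0), mu = pars(1), gam = pars(2);
  const double delta = pars(3), eps = pars(4);
  if (!(delta > 0.0 && eps < 1.0 && delta < eps)) return -1e300;
  if (lambda < 0.0 || mu < 0.0 || gam < 0.0) return -1e300;
  arma::vec pz = cpp_zdist(S, lambda, mu, gam, age);
  arma::vec a(nz), b(nz), c(nz);
  for (int z = 0; z < nz; ++z) {
    const double kap = pars(7 + z);
    if (!(kap > 0.0)) return -1e300;
    const double x = (eps - delta) * z / (2.0 * S) + delta;
    a(z) = kap * x - 1.0;
    b(z) = kap * (1.0 - x) - 1.0;
    c(z) = (pz(z) > 0.0 ? std::log(pz(z)) : -1e300) -
      R::lbeta(kap * x, kap * (1.0 - x));
  }
  const int N = logb.n_elem;
  double total = 0.0;
  arma::vec row(nz);
  for (int i = 0; i < N; ++i) {
    double mx = -arma::datum::inf;
    for (int z = 0; z < nz; ++z) {
      row(z) = a(z) * logb(i) + b(z) * log1mb(i) + c(z);
      if (row(z) > mx) mx = row(z);
    }
    double s = 0.0;
    for (int z = 0; z < nz; ++z) s += std::exp(row(z) - mx);
    total += mx + std::log(s);
    if (!std::isfinite(total)) return -1e300;
  }
  return total;
}

static inline double q_halfnormal(double u, double scale) {
  return scale * R::qnorm(0.5 + 0.5 * u, 0.0, 1.0, 1, 0);
}

// Map a unit-cube point to model parameters through the prior quantile
// functions. pc = (lambda_scale, mu_scale, gamma_scale, delta_a, delta_b,
// epsilon_a, epsilon_b, theta_scale, sigma_scale). The kappa_z block is
// sampled conditional on (theta, sigma): the lognormal is parameterised by
// its population mean theta and s.d. sigma.
// [[Rcpp::export]]
arma::vec cpp_transform(const arma::vec& u, int S, const arma::vec& pc) {
  const int nz = 2 * S + 1;
  if ((int)u.n_elem != 7 + nz) stop("unit-cube point has wrong length");
  arma::vec p(7 + nz);
  p(0) = q_halfnormal(u(0), pc(0));            // lambda
  p(1) = q_halfnormal(u(1), pc(1));            // mu
  p(2) = q_halfnormal(u(2), pc(2));            // gamma
  p(3) = R::qbeta(u(3), pc(3), pc(4), 1, 0);   // delta
  p(4) = R::qbeta(u(4), pc(5), pc(6), 1, 0);   // epsilon
  p(5) = q_halfnormal(u(5), pc(7));            // theta
  p(6) = q_halfnormal(u(6), pc(8));            // sigma
  const double th = p(5), sg = p(6);
  const double mlog = std::log(th * th / std::sqrt(th * th + sg * sg));
  const double slog = std::sqrt(std::log1p(sg * sg / (th * th)));
  for (int z = 0; z < nz; ++z)
    p(7 + z) = R::qlnorm(u(7 + z), mlog, slog, 1, 0);
  return p;
}

// [[Rcpp::export]]
double cpp_loglik_u(const arma::vec& u, const arma::vec& logb,
                    const arma::vec& log1mb, double age, int S,
                    const arma::vec& pc) {
  return cpp_loglik(logb, log1mb, age, S, cpp_transform(u, S, pc));
}

// One likelihood-constrained random walk in the unit cube ('rwalk'):
// Gaussian steps shaped by the live-point covariance (Cholesky factor L),
// scaled by `scale`, reflected at the cube boundary, accepted when the
// transformed point beats the likelihood threshold. Whitening the proposal
// by the live ensemble keeps the walk mixing when posterior widths differ
// by orders of magnitude across dimensions. Uses the R RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_rwalk(const arma::vec& u0, double loglmin, double scale, int walks,
               const arma::mat& L, const arma::vec& logb,
               const arma::vec& log1mb, double age, int S,
               const arma::vec& pc) {
  const int d = u0.n_elem;
  arma::vec u = u0, v(d), eps(d);
  double logl = -arma::datum::inf;
  int nacc = 0;
  for (int it = 0; it < walks; ++it) {
    for (int j = 0; j < d; ++j) eps(j) = R::norm_rand();
    arma::vec stepv = scale * (L * eps);
    for (int j = 0; j < d; ++j) {
      double x = u(j) + stepv(j);
      // reflect into [0, 1]
      while (x < 0.0 || x > 1.0) {
        if (x < 0.0) x = -x;
        if (x > 1.0) x = 2.0 - x;
      }
      v(j) = x;
    }
    double ll = cpp_loglik_u(v, logb, log1mb, age, S, pc);
    if (ll >= loglmin) {  // >= keeps likelihood plateaus moving
      u = v;
      logl = ll;
      ++nacc;
    }
  }
  return List::create(_["u"] = u, _["logl"] = logl, _["naccept"] = nacc);
}

// ---------------------------------------------------------------------------
// Gillespie simulation of the niche with N linked loci.
//
// Events: replacement at total rate lambda*S (the replaced cell adopts the
// replacer's entire epigenotype); per-allele methylation (mu) and
// demethylation (gamma) on non-frozen loci, implemented by uniformization
// over allele slots with acceptance max(mu, gamma)-thinning.
// init: per-locus initial allele count per cell (0 or 2), length nloci.
// frozen: loci that never flip (non-fluctuating contaminants).
// Returns final per-locus z = total methylated alleles across the niche.
// [[Rcpp::export]]
IntegerVector cpp_sim_niche(int S, double lambda, double mu, double gam,
                            double tmax, IntegerVector init,
                            LogicalVector frozen, bool ring) {
  const int N = init.size();
  // a(c, l): methylated allele count of cell c at locus l
  arma::imat a(S, N);
  for (int l = 0; l < N; ++l) a.col(l).fill(init[l]);
  const double mx = std::max(mu, gam);
  int nfree = 0;
  for (int l = 0; l < N; ++l) if (!frozen[l]) ++nfree;
  const double rate_rep = lambda * S;
  const double rate_flip = 2.0 * S * (double)nfree * mx;
  const double rate_tot = rate_rep + rate_flip;
  if (rate_tot <= 0.0) {
    IntegerVector z(N);
    for (int l = 0; l < N; ++l) z[l] = S * init[l];
    return z;
  }
  std::vector<int> free_loci; free_loci.reserve(nfree);
  for (int l = 0; l < N; ++l) if (!frozen[l]) free_loci.push_back(l);
  double t = 0.0;
  for (;;) {
    t += R::exp_rand() / rate_tot;
    if (t > tmax) break;
    if (R::unif_rand() * rate_tot < rate_rep) {
      // replacement: replacer i overwrites target j
      int i = (int)(R::unif_rand() * S); if (i == S) --i;
      int j;
      if (ring) {
        j = (R::unif_rand() < 0.5) ? (i + 1) % S : (i + S - 1) % S;
      } else {
        j = (int)(R::unif_rand() * (S - 1)); if (j == S - 1) --j;
        if (j >= i) ++j;
      }
      a.row(j) = a.row(i);
    } else if (nfree > 0) {
      // candidate allele slot: random cell, random free locus, random allele
      int c = (int)(R::unif_rand() * S); if (c == S) --c;
      int li = (int)(R::unif_rand() * nfree); if (li == nfree) --li;
      int l = free_loci[li];
      int cur = a(c, l);
      bool meth = (R::unif_rand() * 2.0 < (double)cur);
      if (meth) {
        if (R::unif_rand() * mx < gam) a(c, l) = cur - 1;
      } else {
        if (R::unif_rand() * mx < mu) a(c, l) = cur + 1;
      }
    }
  }
  IntegerVector z(N);
  for (int l = 0; l < N; ++l) z[l] = arma::accu(a.col(l));
  return z;
}

// Independent replicate single-locus niches (no linkage): the sampling
// distribution matched by the analytic master-equation model. Supports the
// ring geometry for geometry-robustness comparisons.
// [[Rcpp::export]]
IntegerVector cpp_sim_independent(int S, double lambda, double mu, double gam,
                                  double tmax, int nreps, bool ring) {
  IntegerVector out(nreps);
  std::vector<int> a(S);
  const double mx = std::max(mu, gam);
  const double rate_rep = lambda * S;
  const double rate_flip = 2.0 * S * mx;
  const double rate_tot = rate_rep + rate_flip;
  for (int r = 0; r < nreps; ++r) {
    const int init = (R::unif_rand() < 0.5) ? 2 : 0;
    std::fill(a.begin(), a.end(), init);
    double t = 0.0;
    if (rate_tot > 0.0) for (;;) {
      t += R::exp_rand() / rate_tot;
      if (t > tmax) break;
      if (R::unif_rand() * rate_tot < rate_rep) {
        int i = (int)(R::unif_rand() * S); if (i == S) --i;
        int j;
        if (ring) {
          j = (R::unif_rand() < 0.5) ? (i + 1) % S : (i + S - 1) % S;
        } else {
          j = (int)(R::unif_rand() * (S - 1)); if (j == S - 1) --j;
          if (j >= i) ++j;
        }
        a[j] = a[i];
      } else {
        int c = (int)(R::unif_rand() * S); if (c == S) --c;
        int cur = a[c];
        bool meth = (R::unif_rand() * 2.0 < (double)cur);
        if (meth) {
          if (R::unif_rand() * mx < gam) a[c] = cur - 1;
        } else {
          if (R::unif_rand() * mx < mu) a[c] = cur + 1;
        }
      }
    }
    int z = 0;
    for (int c = 0; c < S; ++c) z += a[c];
    out[r] = z;
  }
  return out;
}
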