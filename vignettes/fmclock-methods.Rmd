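---
title: "Inferring stem cell dynamics from fluctuating methylation clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stem cell dynamics from fluctuating methylation clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmclock)
```

## The biological problem

Adult tissues such as intestinal crypts are maintained by a small pool of
`S` stem cells that stochastically replace one another, so that one lineage
recurrently sweeps the niche (monoclonal conversion). Because these sweeps
leave no permanent genetic record at the timescale of a few years, they are
hard to observe in humans. Certain CpG loci, however, gain and lose
methylation at rates comparable to the replacement dynamics. At such a
*fluctuating CpG* (fCpG), each diploid cell carries 0, 1 or 2 methylated
alleles, and the bulk methylation fraction of a clonal gland — the array
beta value — hops between values `z / 2S` as methylation events occur and
clones expand or contract. The ensemble of fCpG loci therefore behaves as a
recurrent, resettable lineage clock: its distribution across loci in a
single gland encodes the stem cell number `S`, the replacement rate
`lambda`, and the (de)methylation rates `mu` and `gamma`.

## The niche model

`fmclock` models one fCpG locus in a well-mixed niche by the pair
`k` (cells with exactly one methylated allele) and `m` (cells with two),
with `0 <= k + m <= S`, giving `(S+1)(S+2)/2` states. Three processes move
the state:

* replacement: any ordered pair of distinct cells at rate
  `lambda / (S - 1)` (total `lambda * S`), the replaced cell adopting the
  replacer's alleles;
* methylation at rate `mu` per unmethylated allele;
* demethylation at rate `gamma` per methylated allele.

The resulting master equation `dP/dt = T P` is solved by the matrix
exponential; the R path uses `Matrix::expm()` and the compiled likelihood
path uses Armadillo's `expmat`, and the test suite holds them to mutual
agreement. The state ordering is fixed (lexicographic in `(m, k)`) so
generator layouts are reproducible. At `t = 0` the locus is clonal,
homozygously methylated or unmethylated with probability 1/2 each — a
consequence of the embryonic remethylation wave leaving a bimodal
methylation landscape in the founding clone. The observable is
`z = k + 2m`, the methylated-allele count of the niche, obtained by
marginalising the hidden `(k, m)` states.

Two limits anchor intuition and the tests. With replacement off
(`lambda = 0`) the `2S` alleles decouple into independent two-state
flip-flops and the long-time law of `z` is Binomial(`2S`,
`mu / (mu + gamma)`). With very slow flipping the niche stays nearly
clonal and mass concentrates at `z = 0` and `z = 2S`, relaxing at long
times to sharp peaks at 0, `S` and `2S` in 1:2:1 proportion — the
heterozygous clonal state has twice the multiplicity of either homozygous
one. With very fast flipping the clonal record is erased and `z`
approaches Binomial(`2S`, 1/2).

`S = 1` is excluded throughout (the replacement term divides by `S - 1`);
the simulator admits `S >= 2` and the inference grid conventionally starts
at `S = 3`.

## Measurement error

Arrays do not report `z / 2S` exactly: unmethylated loci read slightly
above 0 and saturated loci slightly below 1. Each latent peak `z` is
mapped to a mean beta value by the linear transform
`x = (epsilon - delta) * z / (2S) + delta`, and a measured value around
that peak is Beta(`kappa_z * x`, `kappa_z * (1 - x)`) distributed, with a
per-peak scale ("sample size") `kappa_z`. The crypt likelihood treats loci
as independent given the niche dynamics:

`L = prod_i sum_z P(beta_i | z, delta, epsilon, kappa_z) * P(z | lambda, mu, gamma; t = age)`

The latent distribution is computed once per likelihood call (one matrix
exponential), and the mixture is accumulated by log-sum-exp. Beta values
of exactly 0 or 1 — rare but possible on arrays — are clamped to
`[1e-6, 1 - 1e-6]` with a warning, because the beta density is undefined
at the boundary; nothing is renormalised.

## Priors

All defaults are exposed through `fmc_prior()`:

| parameter | prior | default scale | rationale |
|---|---|---|---|
| `lambda` | half-normal | 1.0 /cell/yr | lineage-tracing estimates of ~1.3 replacements/cell/yr |
| `mu`, `gamma` | half-normal | 0.05 /allele/yr | ~1e-3 errors/division at a ~3-day division time |
| `delta` | Beta(5, 95) | mean 0.05 | background offset small but positive |
| `epsilon` | Beta(95, 5) | mean 0.95 | saturation offset below 1 |
| `theta` | half-normal | 500 | kappa population mean, broad |
| `sigma` | half-normal | 50 | kappa population s.d., broad |

"Scale" of a half-normal is the standard deviation of the underlying
normal (mode at zero). The `kappa_z` are hierarchical: lognormal with
population mean `theta` and standard deviation `sigma`, one `kappa_z` per
latent peak, re-dimensioned when `S` changes. The inference is fairly
insensitive to the `mu`, `gamma` scale, which is why it is a configurable
option rather than a fixed constant.

## Inference

The posterior couples `S` (discrete) with strongly correlated continuous
parameters, and each `S` contributes its own mode; single-chain MCMC
explores this poorly. `fmclock` instead runs static nested sampling
separately for each candidate `S`: live points explore the unit hypercube,
mapped to parameters through the prior quantile functions (the `kappa_z`
coordinates conditional on the sampled `theta`, `sigma`). Replacement
points are generated by a likelihood-constrained Gaussian random walk
reflected at the cube boundary, with the step scale adapted towards 50%
acceptance — the 'rwalk' strategy. Each run returns the log evidence
`log Z(S)` with the classic information-based error `sqrt(H / nlive)`, and
weighted posterior samples.

Evidences combine by softmax: `P(S | beta) = Z(S) / sum_j Z(S_j)`.
Uncertainty on these probabilities is propagated by resampling each
`log Z` from Normal(`log Z`, err) and recomputing the softmax (1,000
draws by default); this Monte-Carlo propagation is the package's own
choice, as is applying 400 live points (configurable; validation runs in
this package use 200) across the whole grid. The model-averaged posterior
draws `S` from `P(S | beta)` and then importance-resamples that run's
weighted samples.

Convergence is checked across independently seeded runs with the
rank-normalized split potential scale reduction statistic
(`fmc_rhat()` / `fmc_convergence()`): equal-weight resampled draws from
each run form the "chains", all draws are replaced by normal scores of
their pooled ranks, each chain is split in half, and the classic
between/within variance ratio is computed. Runs are flagged when any
parameter reaches 1.1.

Numerical choices worth recording: likelihood evaluations returning
non-finite values (offsets out of order, `kappa <= 0`) are scored at
−1e300 rather than −Inf so the sampler can rank them; negative round-off
in propagated probabilities above −1e−12 is clipped and renormalised,
anything larger is an error; nested-sampling termination uses an
estimated-remaining-evidence tolerance of `dlogz = 0.05`; random-walk
steps that find no improvement trigger up to 50 restarts from other live
points before the run aborts with a diagnostic error. All randomness runs
through R's RNG (also from compiled code), so a fit is reproducible
bit-for-bit given its seed.

## The simulator and what it does (not) capture

`fmc_simulate_niche()` is an exact Gillespie simulation: replacement at
total rate `lambda * S` (well-mixed: uniform ordered pair; ring: a random
cell overwrites a random one of its two neighbours — a convention, since
only "neighbouring cells" is specified by the ring model), and per-allele
flips implemented by uniformization over allele slots with
max(`mu`, `gamma`) thinning. Replacement copies the entire linked
epigenotype, so simulated loci within one crypt are correlated exactly as
in tissue; with `linked = FALSE` each locus lives in its own niche, which
is the independence regime the analytic model describes. A configurable
fraction of loci can be frozen at their clonal initial state to emulate
non-fluctuating contaminants (the simplest reading of "not fluctuating";
a regulated-at-50% variant would also be defensible but is not the
default).

Linkage is the main feature real data have that the *likelihood* ignores:
the analytic model matches the per-peak means of linked simulations but
understates across-crypt variability, so credible intervals from the
independence likelihood are marginally too narrow. Passing tests on
synthetic crypts therefore demonstrate correctness of the inference under
its own assumptions, not immunity to linkage, selection at fCpG loci, or
array artefacts beyond the beta-mixture noise model.

Synthetic validation crypts use `S = 5`, `lambda = 1.0`,
`mu = gamma = 0.05`, age 60 (a typical donor age; the validation-figure
age is not stated anywhere, so it is a package default exposed as an
argument), `N = 1794` loci, noise `delta = 0.04`, `epsilon = 0.92`,
`kappa = 100`. The three regimes — "too slow" (`5e-4`), "just right"
(`0.05`) and "too fast" (`0.5`) — reproduce, respectively: nearly all
loci near 0 or 1; the characteristic trimodal "W" shape; and a unimodal
distribution centred near `(delta + epsilon) / 2 = 0.48`.

## Fixation times

`fmc_fixation_time()` reports the expected time for one labelled stem
lineage to sweep the niche, conditional on it doing so. The labelled count
is a birth-death chain with symmetric rates `lambda * n * (S - n) / (S - 1)`;
the conditioned (Doob h-transform, `h(n) = n / S`) chain's mean absorption
time is solved as a linear system, or estimated by Gillespie runs that
reach fixation. Both routes scale as `1 / lambda` and are cross-checked in
the tests; for `S = 2` the closed form is `1 / (2 * lambda)`.

## fCpG selection

`fmc_filter_probes()` retains type II, autosomal, non-cross-reactive,
open-sea probes (further than 4 kb from a CpG island) and — when
intensities are available — loci with total intensity above 1,200 in every
sample (dropping the locus if any sample fails; a per-locus-mean variant
would be the natural alternative). `fmc_score_heterogeneity()` computes,
per locus, the standard deviation of beta across each individual's glands
and averages across individuals: fluctuating loci diverge between glands
of one person, regulated loci do not. `fmc_select_fcpgs()` keeps the top
5% by this score — the threshold is a count cut (`floor(n * 0.05)`) with
ties broken by locus id for determinism — then drops loci whose cohort
mean beta lies outside `[0.40, 0.60]`; the bounds are inclusive because
the removal rule excludes only means strictly below 0.4 or above 0.6.
Probe-level filters are applied before the heterogeneity cut. An
alternative heterogeneity metric (between-sample variance over the whole
cohort) differs mainly in how it treats between-individual spread; the
within-individual form is the default because it is the one that directly
expresses "independent evolution per gland".

As an optional sanity analysis on real arrays (not implemented as code
here): X-chromosome fCpGs in males, which carry a single allele, should
show bimodal "U-shaped" rather than trimodal "W-shaped" distributions in
clonal samples — a useful check that the signal is clonal rather than
regulatory.

## Blood

Whole blood averages over very many stem lineages, so fluctuating loci sit
tightly around 50% methylation; `fmc_blood_panel()` selects loci with
cohort mean beta in `[0.40, 0.60]`, and `fmc_sample_variance()` (population
variance across panel loci) summarises one sample. Clonal hematopoiesis
raises this variance: the expanding clone's loci share the founder's
0/50/100% pattern. `fmc_simulate_hematopoiesis()` captures the mechanism
with deliberately simple ingredients — independent background lineages
whose diploid loci flip allele-wise (defaults: 2,000 lineages in tests,
flip rate 0.05/allele/yr), one founder clone whose blood fraction grows
logistically, and a clone bulk beta that relaxes from the founder state
toward 0.5 as within-clone fluctuations desynchronise. The quantitative
settings are package choices (the source analysis's supplementary
parameters are not public), so only qualitative orderings are asserted
anywhere: variance rises with clone fraction; fast expansions (years) are
W-shaped; slow expansions raise variance without the W; polyclonal blood
is low and stable.

## Problem sizes used in validation

The packaged validation uses one synthetic crypt at the full panel size
(1,794 loci), an inference grid `S in [3, 8]` with 200 live points and
four independently seeded runs for the convergence check; oracle
comparisons between the analytic law and Gillespie frequencies use
20,000 replicate niches (1.5 million per arm for the ring-geometry
comparison, where the true total-variation distance of ~0.049 needs a
small Monte-Carlo error to be resolved against its 0.05 bound). The
selection fixture is a 3-individual x 4-gland cohort of 2,000 loci with
200 planted fluctuating loci. These sizes were chosen to make every check
sharp at desk scale; all are arguments, not constants.

## Known limitations

* The likelihood ignores locus linkage (see above) — intervals are
  slightly narrow.
* Dimensionality grows as `S^2`; the dense matrix exponential is
  comfortable to `S ~ 20` but the approach is not meant for large niches.
* Rates are assumed constant over life; estimates are lifetime averages
  per gland.
* The spatial (off-lattice crypt) geometry is represented only by the
  ring variant of the simulator, which bounds the effect of geometry on
  the methylation distribution but does not model transit-amplifying
  flow.
* No IDAT handling or normalisation: the package consumes beta matrices.
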