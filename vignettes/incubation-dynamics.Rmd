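---
title: "Incubation-period distributions from Moran dynamics on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incubation-period distributions from Moran dynamics on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranincub)
```

## The model

Incubation periods of many diseases — typhoid, measles, polio, several
cancers — are right-skewed and approximately lognormal, with geometric
standard deviations ("dispersion factors") clustered around 1.1–1.5. This
package implements a stochastic explanation that needs no host or pathogen
heterogeneity: the incubation period is modelled as the time a clone of
pathogenic *invaders* needs to take over a network of healthy *residents*
under Moran dynamics.

A network of `N` nodes represents cells in a host compartment (a well-mixed
microbiome as a complete graph, bone marrow as a 3D lattice, an epithelial
sheet as a 2D lattice). Invaders carry relative fitness `r`; residents have
fitness 1. Two update rules are supported:

* **Birth-death (Bd)**: a node is picked from the whole population with
  probability proportional to fitness; a uniformly random neighbour adopts
  its type.
* **Death-birth (Db)**: a node is picked to die with probability
  proportional to `1/fitness`; it adopts the type of a uniformly random
  neighbour.

Starting from a dose of invaders on random nodes, the process ends at
fixation (all invaders) or extinction (all residents). The incubation period
is the number of elementary update events until the invader count reaches a
threshold — all of `N`, or a fraction `f` of it. Time deliberately counts
*every* event, including no-change events (invader replacing invader,
resident replacing resident): under that convention the waiting time between
successive invader-count increments on solvable graphs is geometric, which
is what makes the model analytically tractable. Physical time is a
disease-specific rescaling of these division events and is out of scope.

Only Bd and Db are implemented; the other four fitness-capitalisation
variants (bD, dB, BD, DB), one-to-many viral dynamics and continuous-time
embeddings are deliberately excluded.

## Two mechanisms of right skew

**Infinitely fit invaders (coupon collection).** At `r = Inf` only invaders
reproduce and the invader count never decreases. On the complete graph the
probability of adding an invader when `m` are present is
`p_m = (N - m)/(N - 1)`, so the fixation time is

    T = sum_{k=1}^{N-1} Geo(k / (N - 1)),

the coupon collector's waiting time: the last few healthy nodes take a long
time to be found blindly, which skews `T` to the right. As `N` grows,
`(T - mu_N)/N` converges to a Gumbel(`-gamma`, 1) law with
`mu_N = (N-1) H_{N-1}` (`limit_law("complete", N)`); the star graph with `N`
spokes converges to the same Gumbel under the centering
`N^2 log N + (gamma - 1) N^2` and scale `N^2`. The 1D ring grows as a
contiguous arc, `T = Geo(1) + sum_{m=2}^{N-1} Geo(1/m)`, and is
asymptotically *normal* (Lindeberg–Feller); so are 2D lattices. Lattices of
dimension `d >= 3` are right-skewed with asymptotic skewness
`2 zeta(3 eta)/zeta(2 eta)^{3/2}`, `eta = 1 - 1/d` (`lattice_skew()`), which
increases with `d` to the Gumbel skewness `12 sqrt(6) zeta(3)/pi^3`; `d = 2`
is the critical dimension.

`sample_coupon_collector()` and `sample_ring_growth()` draw from the exact
geometric-sum representations and are identical in distribution to the
per-step engine (the test suite verifies this by two-sample
Kolmogorov–Smirnov at small `N` and at `N = 150` / `N = 75`).

**Neutral invaders (conditioned random walks).** At `r = 1` the invader
count performs an unbiased random walk with two absorbing states. Only
walks that reach `N` produce symptoms, so the ensemble is conditioned on
fixation (`run_conditioned_ensemble()` uses plain rejection, faithful to
that definition; the acceptance fraction on the complete graph is the
neutral fixation probability `1/N`). Conditioning favours early growth but
still admits long meandering excursions, producing right skew on high- and
low-dimensional networks alike, with larger dispersion factors (~1.7) than
coupon collection gives (~1.1–1.4).

## The dispersion factor

For a positive sample, `dispersion_factor()` returns the geometric mean
`mu_G = exp(mean(log x))` and geometric standard deviation
`sigma_G = exp(sqrt(sum(log(x/mu_G)^2)/(n-1)))`. `log(sigma_G)` is the MLE
of the scale of an unshifted lognormal; `sigma_G` is dimensionless and
scale-invariant, which makes it comparable across diseases with different
characteristic times. The survey in `dispersion_table()` reproduces the
model's headline quantitative claim: across complete, star, lattice,
Erdős–Rényi, small-world, k-regular and scale-free topologies, infinitely
fit invaders give `sigma_G` about 1.1–1.4 and neutral invaders about
1.66–1.79. Confidence intervals are nonparametric percentile bootstraps
(2000 resamples by default); the interval method behind the published
+-values is not documented, so third-decimal differences are expected.

## Truncated takeover thresholds

Symptoms rarely require complete takeover. With threshold `ceiling(f * N)`,
Bd and Db behave very differently at `r = Inf`
(`run_truncation_sweep()`): the slow phase of Bd coupon collection is at the
*end* of the invasion, so any `f < 1` truncates it and collapses the Gumbel
toward a normal; Db's slow phase is at the *beginning* (finding one of the
few invaders to reproduce), so its Gumbel persists for every `f > 0`.

A finite-size caveat that matters for testing: the collapse of the Bd skew
is asymptotic. The exact skewness of the truncated geometric sum at
`N = 500` is 0.695 for `f = 0.1` and 0.191 for `f = 0.9` (still 0.214 for
`f = 0.1` at `N = 5000`): truncation at small `f` leaves a sum dominated by
near-certain steps — essentially a Poisson-like count whose skew decays only
like `1/(f sqrt(N))`. The robust, `N`-stable statement is the *pattern*:
truncated Bd skew is a small fraction of the `f = 1` skew and far below the
matched Db skew, and that is what the package's property tests assert at
`N = 300`–`500`.

## Heterogeneity and variable populations

`run_heterogeneous_ensemble()` layers host-to-host variability over the
complete-graph model (baseline `N = 500`, `r = 10`, dose 1, `f = 1`):
fitness `r ~ Gamma(shape = 10)`, threshold uniform on `{2, ..., N}` or
`ceiling(U(0,1) * N)`, and dose `Poisson(10) + 1`. The Gamma rate defaults
to 1 so the heterogeneous fitness has mean 10, matching the homogeneous
baseline; only the shape is treated as the scenario's defining parameter. Parameter draws with
`dose >= threshold` are redrawn; each attempt redraws parameters and runs
one trial, and extinct attempts are rejected, so the ensemble is conditioned
jointly over parameters and paths (the run-rejection procedure described for
these scenarios). Fitness and threshold heterogeneity visibly increase the
right skew. Dose heterogeneity keeps the distribution right-skewed but can
nudge the skewness slightly *below* the dose-1 baseline, because a larger
initial dose removes part of the conditioned-walk variability; the
qualitative claim (skew persists) is robust, the "never decreases" reading
is not, and the acceptance check reports whatever the run produces.

`run_variable_population()` adds population change on the complete graph
(new nodes are adjacent to everyone, so completeness is preserved — the
reason this runner is restricted to that family): per time step, first the
population event (grow or shrink by one resident with constant probability
`1/N`, or a forced ±1 random walk), then one Moran update; the tick counts
one step. Growth accentuates the right skew, shrinkage lessens it (global
shrinkage speeds up the final coupon collection), and the random-walk mode
is the most extreme.

## Numerical design

* **Engine.** One C++ per-step engine (O(1) per event via class-membership
  lists) for arbitrary graphs, plus an exact count-based path for the
  complete graph, used by the heterogeneity and variable-population runners.
  `r = Inf` is a dedicated code path (uniform choice over invaders or
  residents), not a large float.
* **Randomness.** All C++ code draws from R's RNG, so a single `set.seed()`
  (or the `seed` arguments / `--seed` flags) makes every run, including
  graph generation and rejected trials, bit-reproducible. Rejected trials
  consume the stream, so conditioned results depend on the rejection
  history by design.
* **Random graphs.** Families are built with igraph; disconnected draws are
  resampled (bounded retries) because fixation is ill-defined across
  components. Lattices are periodic in every dimension: periodicity gives
  exact translation invariance and makes the 1D lattice a ring (2D/3D
  summary values may be mildly sensitive to this boundary choice). Random-family ensembles draw a *fresh* graph per trial, so
  they average over the graph distribution; a published value measured on
  one fixed realisation can sit a few percent away (observed for the
  scale-free family, where fixed 100-node realisations span dispersion
  factors of roughly 1.34–1.41).
* **Small-world backbone.** The Newman–Watts–Strogatz shortcut probability
  is 0.25 per backbone edge; the backbone joins each node to its two nearest
  neighbours per side (degree 4), a conventional choice since only the
  shortcut probability is specified.
* **Fits.** `fit_gumbel_moments()` matches mean and sd in closed form;
  `fit_shifted_lognormal_moments()` matches three moments via the unique
  real root of the depressed cubic `u^3 + 3u = skew`, and declines
  (`converged = FALSE`) on non-right-skewed samples. Both are exact on their
  matched moments by construction; maximum-likelihood fitting and
  Gumbel-vs-lognormal model selection are out of scope (the two families are
  intentionally hard to tell apart here).
* **Limit-law standardisation.** The complete graph uses the exact harmonic
  centering rather than `N log N + N gamma` (much better finite-`N`
  Kolmogorov–Smirnov behaviour; the asymptotic form remains available). The
  star's analytic constants converge slowly — at 75 spokes the analytic
  scale `N^2` is ~20% away from the true sd — so finite-`N` star samples are
  compared to the Gumbel *shape* after empirical standardisation, the same
  normalisation used for families without closed-form constants. The ring's
  normal limit is likewise asymptotic: the exact skewness of the ring sum is
  0.302 at `N = 75`, detectable by a KS test at 10^4 samples even though the
  distribution is visually normal.

## Problem sizes used by the tests

The packaged checks run at desk scale, chosen to keep the full suite in a
few minutes while leaving the published comparisons statistically
meaningful: 10^4 replicates for the infinite-fitness dispersion targets
(complete `N = 150`, star 75 spokes, ring `N = 75`, Erdős–Rényi `N = 115`,
scale-free `N = 100`), 5×10^3 conditioned replicates for the neutral
complete/ring targets at `N = 50`, 5×10^3 for truncation sweeps at
`N = 500`, and 2×10^3 for heterogeneity and population scenarios. The
original survey used 10^6 replicates (10^5 for large lattices); at 10^4
replicates the bootstrap CI on a dispersion factor is roughly ±0.005–0.01,
so comparisons are made at that resolution.

## What the generators do and do not emulate

The synthetic ensembles reproduce the *model's* study conditions exactly:
network families at the published sizes, dose-1 initialisation, rejection
conditioning, truncation and heterogeneity distributions. They do not
emulate features of real incubation data — measurement in days, interval
censoring, reporting delays, dose uncertainty correlated with exposure
route, or within-host spatial structure beyond the stylised graph families —
so passing tests validate the implementation and the model's internal
claims, not the model's fit to any particular disease. The distribution
fitting utilities (`read_incubation_times()`, `fit_gumbel_moments()`,
`fit_shifted_lognormal_moments()`, `dispersion_factor()`) are the bridge to
real data.
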