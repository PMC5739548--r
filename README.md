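# moranincub

Incubation periods of diseases as different as typhoid, measles and
radiation-induced leukemia share a striking statistical signature: they are
right-skewed, approximately lognormal, with geometric standard deviations
("dispersion factors") around 1.1–1.5. `moranincub` implements an
evolutionary-graph-theory explanation of that pattern for researchers in
within-host disease modelling and evolutionary dynamics: the incubation
period is the time a pathogenic invader clone needs to take over a network
of `N` healthy resident cells under Moran Birth-death (Bd) or Death-birth
(Db) dynamics, counted in elementary replacement events.

The skew needs no host or pathogen heterogeneity. It arises from two
stochastic mechanisms:

* **Coupon collection** (highly fit invaders, `r -> Inf`): on the complete
  graph the fixation time is an exact sum of geometric variables,
  `T = Σ_{k=1}^{N-1} Geo(k/(N-1))`, whose standardized law converges to a
  Gumbel(−γ, 1) — right-skewed, easily mistaken for a lognormal. The star
  graph is also Gumbel; 1D rings and 2D lattices are asymptotically normal;
  lattices of dimension `d ≥ 3` have skewness `2ζ(3η)/ζ(2η)^{3/2}` with
  `η = 1 − 1/d`, rising to the Gumbel skewness `12√6 ζ(3)/π³` as `d → ∞`.
* **Conditioned random walks** (neutral invaders, `r = 1`): the invader
  count is an unbiased walk conditioned to hit `N` before 0; the
  conditioning makes fast takeovers typical but long excursions possible,
  producing right skew on essentially every topology, with larger
  dispersion factors (≈1.7).

The package provides seeded constructors for the nine network families
studied (complete, star, periodic 1D/2D/3D lattices, Erdős–Rényi,
Newman–Watts–Strogatz small-world, random k-regular, Barabási–Albert
scale-free), a fast per-step simulation engine with exact geometric-sum
samplers for solvable graphs, the asymptotic limit laws, dispersion-factor
statistics with bootstrap confidence intervals, method-of-moments Gumbel and
shifted-lognormal fits, and experiment runners for truncated takeover
thresholds (`f < 1`), heterogeneous fitness/threshold/dose, and growing,
shrinking or randomly varying populations.

## Worked example

```r
library(moranincub)
set.seed(42)

# Infinitely fit invader on a complete graph of N = 150 cells:
# exact coupon-collector sampler, identical in law to per-step simulation.
ens <- sample_coupon_collector(150, 10000)
dispersion_factor(ens$times)
#> <summary_stats> n=10000  mean=831.256  sd=188.219  skew=1.1652  geo_mean=811.962  dispersion=1.2379

# The standardized times follow the Gumbel(-gamma, 1) limit law.
law <- limit_law("complete", 150)
law
#> <limit_law> gumbel: location 832.093, scale 150
ks_distance(standardize_by_law(ens$times, law), gumbel_cdf)
#> [1] 0.0125

# Neutral invader on a complete graph of N = 50, conditioned on takeover:
# the acceptance fraction is the neutral fixation probability 1/N = 0.02.
net <- make_network("complete", n = 50)
neutral <- run_conditioned_ensemble(simulation_spec(net, "Bd", fitness = 1), 2000)
2000 / (2000 + neutral$n_rejected)
#> [1] 0.0201
dispersion_factor(neutral$times)
#> <summary_stats> n=2000  mean=2416.64  sd=1352.26  skew=1.7011  geo_mean=2110.63  dispersion=1.6751
```

The two dispersion factors — ≈1.24 for the fit invader, ≈1.68 for the
neutral one — bracket the 1.1–1.5 range reported for real infectious
diseases and reproduce the model's survey values (1.2386 and 1.6629 at 10⁶
replicates). `fit_shifted_lognormal_moments(neutral$times)` fits the
noncentral lognormal that such data would traditionally be summarized with.

A thin command-line wrapper over the same functions ships in
`inst/cli/moranincub.R`:

```sh
Rscript inst/cli/moranincub.R simulate --graph complete --n 150 --rule Bd \
    --r inf --reps 10000 --seed 1 --out times.csv
Rscript inst/cli/moranincub.R theory --family ring_1d --n 75
Rscript inst/cli/moranincub.R fit --input times.csv --family gumbel
Rscript inst/cli/moranincub.R table1 --reps 10000 --reps-neutral 3000 --seed 1
```

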