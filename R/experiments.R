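#' Conditioned ensemble with heterogeneous fitness, threshold and dose
#'
#' Emulates host-to-host heterogeneity on top of the Moran model on a
#' complete graph of `N` nodes. Per attempt, the invader fitness, the
#' takeover threshold and/or the initial dose can each be drawn afresh:
#'
#' * `fitness_dist = "gamma"`: `r ~ Gamma(shape, rate)` (defaults
#'   shape 10, rate 1, so the mean matches the baseline `r = 10`);
#' * `threshold_dist = "uniform_integer"`: threshold uniform on `{2, ..., N}`;
#' * `threshold_dist = "uniform_fraction"`: `f ~ Uniform(0, 1)` and the
#'   threshold is `ceiling(f * N)`;
#' * `dose_dist = "shifted_poisson"`: dose `~ Poisson(dose_mean) + dose_shift`.
#'
#' Draws with `dose >= threshold` (or a zero fitness) are rejected and
#' redrawn; trials in which the invaders go extinct are rejected and the
#' whole attempt (parameter draw plus trial) repeated, so the ensemble is
#' conditioned on takeover. With all distributions `"none"` this reduces
#' exactly to a conditioned ensemble at the baseline parameters.
#'
#' @param n_samples Number of conditioned takeover times.
#' @param N Complete-graph size (baseline 500).
#' @param fitness Baseline invader fitness (used when `fitness_dist = "none"`).
#' @param dose Baseline dose.
#' @param f Baseline takeover fraction.
#' @param rule `"Bd"` or `"Db"`.
#' @param fitness_dist,threshold_dist,dose_dist Heterogeneity switches, see
#'   Details.
#' @param fitness_shape,fitness_rate Gamma parameters for the fitness draw.
#' @param dose_mean,dose_shift Shifted-Poisson parameters for the dose draw.
#' @param seed Optional integer seed.
#' @param max_attempts Safety cap on total attempts.
#' @return A `sample_set`; `spec` records the scenario.
#' @examples
#' s <- run_heterogeneous_ensemble(200, N = 100, fitness_dist = "gamma", seed = 1)
#' sample_skewness(s$times) # right-skewed
#' @export
run_heterogeneous_ensemble <- function(n_samples, N = 500L, fitness = 10,
                                       dose = 1L, f = 1, rule = c("Bd", "Db"),
                                       fitness_dist = c("none", "gamma"),
                                       threshold_dist = c("none", "uniform_integer", "uniform_fraction"),
                                       dose_dist = c("none", "shifted_poisson"),
                                       fitness_shape = 10, fitness_rate = 1,
                                       dose_mean = 10, dose_shift = 1L,
                                       seed = NULL,
                                       max_attempts = 1000 * n_samples) {
  rule <- match.arg(rule)
  fitness_dist <- match.arg(fitness_dist)
  threshold_dist <- match.arg(threshold_dist)
  dose_dist <- match.arg(dose_dist)
  stopifnot(n_samples >= 1, N >= 3)
  if (!is.null(seed)) set.seed(seed)
  base_threshold <- as.integer(ceiling(f * N))
  if (dose_dist == "none" && dose >= base_threshold) {
    stop("baseline dose must be smaller than the takeover threshold", call. = FALSE)
  }
  if (dose_dist == "shifted_poisson" && dose_shift >= N) {
    stop("dose distribution lies entirely at or above the network size", call. = FALSE)
  }

  draw <- function() {
    for (i in 1:10000) {
      r <- if (fitness_dist == "gamma") {
        stats::rgamma(1L, shape = fitness_shape, rate = fitness_rate)
      } else {
        fitness
      }
      thr <- switch(threshold_dist,
        none = base_threshold,
        uniform_integer = sample(2:N, 1L),
        uniform_fraction = as.integer(ceiling(stats::runif(1L) * N))
      )
      dse <- if (dose_dist == "shifted_poisson") {
        stats::rpois(1L, dose_mean) + as.integer(dose_shift)
      } else {
        as.integer(dose)
      }
      if (r > 0 && dse >= 1L && dse < thr) {
        return(list(r = r, threshold = thr, dose = dse))
      }
    }
    stop("could not draw valid (fitness, threshold, dose) in 10000 tries", call. = FALSE)
  }

  times <- numeric(n_samples)
  got <- 0L
  attempts <- 0
  rejected <- 0
  r_inf <- is.infinite(fitness) && fitness_dist == "none"
  while (got < n_samples) {
    if (attempts >= max_attempts) {
      stop("exceeded ", max_attempts, " attempts with only ", got,
        " takeovers",
        call. = FALSE
      )
    }
    attempts <- attempts + 1
    p <- draw()
    res <- cpp_complete_trial(
      as.integer(N), rule_code(rule),
      if (r_inf) 1 else p$r, r_inf,
      p$dose, p$threshold, 0L, 0, 1e12
    )
    if (res[1] > 0) {
      got <- got + 1L
      times[got] <- res[2]
    } else {
      rejected <- rejected + 1
    }
  }
  spec <- list(
    scenario = "heterogeneous", family = "complete", n_nodes = as.integer(N),
    rule = rule, fitness = if (is.infinite(fitness)) "Inf" else fitness,
    dose = dose, f = f,
    fitness_dist = fitness_dist, threshold_dist = threshold_dist,
    dose_dist = dose_dist
  )
  new_sample_set(times, spec, rejected)
}

#' Conditioned ensemble with a non-static population
#'
#' Simulates Bd/Db dynamics on a complete graph whose resident population
#' changes over time. At every time step the population event is applied
#' first, then one Moran update; the tick counts as a single step:
#'
#' * `"grow"`: with constant probability `1/N` a new resident node appears,
#'   adjacent to all preexisting nodes (the graph stays complete);
#' * `"shrink"`: with constant probability `1/N` a uniform random resident is
#'   removed (a no-op if no residents remain);
#' * `"random_walk"`: every step a resident node is added or removed, each
#'   with probability 1/2;
#' * `"static"`: no population events -- identical in law to
#'   [run_conditioned_ensemble()] on the complete graph.
#'
#' A trial ends when the invaders equal the current population size
#' (takeover) or hit zero (extinct, rejected). `1/N` uses the initial size.
#'
#' @inheritParams run_heterogeneous_ensemble
#' @param mode Population mode, see Details.
#' @return A `sample_set`.
#' @examples
#' s <- run_variable_population(200, N = 100, mode = "grow", seed = 1)
#' @export
run_variable_population <- function(n_samples, N = 500L, fitness = 10,
                                    dose = 1L,
                                    mode = c("static", "grow", "shrink", "random_walk"),
                                    rule = c("Bd", "Db"), seed = NULL,
                                    max_attempts = 1000 * n_samples) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  stopifnot(n_samples >= 1, N >= 3, dose >= 1, dose < N)
  if (!is.null(seed)) set.seed(seed)
  pop_mode <- match(mode, c("static", "grow", "shrink", "random_walk")) - 1L
  res <- cpp_complete_ensemble(
    as.integer(N), rule_code(rule),
    if (is.infinite(fitness)) 1 else fitness, is.infinite(fitness),
    as.integer(dose), as.integer(N), as.integer(n_samples), max_attempts,
    pop_mode, 1 / N, 1e12
  )
  spec <- list(
    scenario = "variable_population", family = "complete",
    n_nodes = as.integer(N), rule = rule,
    fitness = if (is.infinite(fitness)) "Inf" else fitness,
    dose = as.integer(dose), mode = mode
  )
  new_sample_set(res$times, spec, res$n_rejected)
}

#' Skewness of takeover times across truncation fractions
#'
#' Runs conditioned ensembles for each takeover fraction `f` and reports the
#' skewness of the takeover-time distribution, with a rough shape label:
#' `|skew| < 0.15` is called normal-like and `skew > 0.3` Gumbel-like (these
#' thresholds are package conventions for summarising the sweep, not sharp
#' classifications). At infinite fitness under Bd the full-fixation Gumbel
#' becomes normal once `f < 1` (the slow coupon-collector tail at the end of
#' the invasion is truncated away), while under Db the Gumbel persists for
#' all `f > 0` (its slow phase is at the start of the invasion).
#'
#' @param network A [make_network()] object.
#' @param rule `"Bd"` or `"Db"`.
#' @param f_values Takeover fractions in (0, 1].
#' @param n_samples Replicates per fraction.
#' @param fitness Invader fitness (default infinite).
#' @param dose Initial invaders.
#' @param seed Optional integer seed.
#' @return List with `samples` (named list of `sample_set`s) and `table`
#'   (data.frame: `f`, `threshold`, `skewness`, `shape`).
#' @examples
#' net <- make_network("complete", n = 100)
#' run_truncation_sweep(net, "Bd", c(0.1, 1), 500, seed = 1)$table
#' @export
run_truncation_sweep <- function(network, rule = c("Bd", "Db"),
                                 f_values = c(0.1, 0.9, 1), n_samples = 5000L,
                                 fitness = Inf, dose = 1L, seed = NULL) {
  stopifnot(inherits(network, "moran_network"))
  rule <- match.arg(rule)
  if (any(f_values <= 0 | f_values > 1)) stop("'f_values' must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  samples <- list()
  rows <- lapply(f_values, function(f) {
    spec <- simulation_spec(network, rule, fitness, dose = dose, f = f)
    ens <- run_conditioned_ensemble(spec, n_samples)
    samples[[sprintf("f=%g", f)]] <<- ens
    sk <- sample_skewness(ens$times)
    data.frame(
      f = f, threshold = spec$threshold, skewness = sk,
      shape = classify_shape(sk), stringsAsFactors = FALSE
    )
  })
  list(samples = samples, table = do.call(rbind, rows))
}

classify_shape <- function(skew) {
  if (abs(skew) < 0.15) "normal_like" else if (skew > 0.3) "gumbel_like" else "intermediate"
}

# Survey scenarios behind the dispersion-factor table: network family +
# parameters (from the corresponding figure-level setups) for each fitness
# regime, and whether an exact sampler is available at r = Inf.
table_scenarios <- function() {
  list(
    complete = list(
      inf = list(args = list(family = "complete", n = 150), fast = "coupon"),
      neutral = list(args = list(family = "complete", n = 50))
    ),
    star = list(
      inf = list(args = list(family = "star", spokes = 75)),
      neutral = list(args = list(family = "star", spokes = 25))
    ),
    ring_1d = list(
      inf = list(args = list(family = "ring_1d", n = 75), fast = "ring"),
      neutral = list(args = list(family = "ring_1d", n = 50))
    ),
    lattice_2d = list(
      inf = list(args = list(family = "lattice_2d", dims = c(60, 60))),
      neutral = list(args = list(family = "lattice_2d", dims = c(7, 7)))
    ),
    lattice_3d = list(
      inf = list(args = list(family = "lattice_3d", dims = c(11, 11, 11))),
      neutral = list(args = list(family = "lattice_3d", dims = c(4, 4, 4)))
    ),
    erdos_renyi = list(
      inf = list(args = list(family = "erdos_renyi", n = 115, p = 0.5), fresh = TRUE),
      neutral = list(args = list(family = "erdos_renyi", n = 25, p = 0.5), fresh = TRUE)
    ),
    small_world = list(
      inf = list(args = list(family = "small_world", n = 75, p = 0.25), fresh = TRUE),
      neutral = list(args = list(family = "small_world", n = 25, p = 0.25), fresh = TRUE)
    ),
    k_regular = list(
      inf = list(args = list(family = "k_regular", n = 100, k = 3), fresh = TRUE),
      neutral = list(args = list(family = "k_regular", n = 22, k = 3), fresh = TRUE)
    ),
    scale_free = list(
      inf = list(args = list(family = "scale_free", n = 100, m = 3), fresh = TRUE),
      neutral = list(args = list(family = "scale_free", n = 22, m = 3), fresh = TRUE)
    )
  )
}

#' Run one dispersion-table scenario
#'
#' Draws a conditioned ensemble of full-fixation times for one network family
#' at one fitness regime, using the family sizes of the figure-level setups
#' (e.g. complete N = 150, star 75 spokes, ring N = 75 at infinite fitness;
#' complete N = 50, ring N = 50 at neutral fitness). Random graph families
#' use a fresh graph per trial. For the complete graph and the ring at
#' infinite fitness the exact geometric-sum samplers are used unless
#' `fast = FALSE`.
#'
#' @param family One of the nine families of [make_network()].
#' @param fitness `Inf` or a positive number (the survey uses `Inf` and 1).
#' @param n_samples Number of conditioned takeover times.
#' @param rule `"Bd"` or `"Db"`.
#' @param fast Allow exact samplers where available.
#' @param seed Optional integer seed.
#' @param max_attempts Safety cap on total attempts.
#' @return A `sample_set`.
#' @examples
#' s <- run_table_scenario("ring_1d", Inf, 1000, seed = 1)
#' dispersion_factor(s$times)
#' @export
run_table_scenario <- function(family, fitness = Inf, n_samples = 10000L,
                               rule = "Bd", fast = TRUE, seed = NULL,
                               max_attempts = 1000 * n_samples) {
  scen_all <- table_scenarios()
  family <- match.arg(family, names(scen_all))
  regime <- if (is.infinite(fitness)) "inf" else "neutral"
  scen <- scen_all[[family]][[regime]]
  if (!is.null(seed)) set.seed(seed)

  if (fast && is.infinite(fitness) && rule == "Bd" && !is.null(scen$fast)) {
    n <- scen$args$n
    return(if (scen$fast == "coupon") {
      sample_coupon_collector(n, n_samples)
    } else {
      sample_ring_growth(n, n_samples)
    })
  }

  make1 <- function() do.call(make_network, scen$args)
  net <- make1()
  spec <- simulation_spec(net, rule, fitness, dose = 1L, f = 1)
  run_conditioned_ensemble(
    spec, n_samples,
    max_attempts = max_attempts,
    fresh_network = if (isTRUE(scen$fresh)) make1 else NULL
  )
}

#' Dispersion factors across network families and fitness regimes
#'
#' Reproduces the dispersion-factor survey: for each requested network family
#' and for infinite and neutral invader fitness, draws a conditioned ensemble
#' of full-fixation times ([run_table_scenario()]) and reports the geometric
#' standard deviation with a nonparametric bootstrap confidence interval.
#'
#' @param n_samples Replicates for the infinite-fitness ensembles.
#' @param n_samples_neutral Replicates for the (slower, conditioned) neutral
#'   ensembles.
#' @param families Subset of the nine family names (default all).
#' @param fitness_levels Which regimes to run: subset of `c("inf", "neutral")`.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return Data frame with columns `family`, `fitness`, `n_nodes`, `reps`,
#'   `dispersion`, `lower`, `upper`.
#' @examples
#' dispersion_table(500, 300, families = c("complete", "ring_1d"), seed = 1)
#' @export
dispersion_table <- function(n_samples = 10000L, n_samples_neutral = 3000L,
                             families = names(table_scenarios()),
                             fitness_levels = c("inf", "neutral"),
                             n_boot = 1000L, conf = 0.95, seed = NULL) {
  families <- match.arg(families, names(table_scenarios()), several.ok = TRUE)
  fitness_levels <- match.arg(fitness_levels, c("inf", "neutral"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (fam in families) {
    for (lev in fitness_levels) {
      fit <- if (lev == "inf") Inf else 1
      reps <- if (lev == "inf") n_samples else n_samples_neutral
      ens <- run_table_scenario(fam, fit, reps)
      ci <- bootstrap_ci(ens$times, n_boot = n_boot, conf = conf)
      n_nodes <- if (inherits(ens$spec, "simulation_spec")) {
        ens$spec$network$n_nodes
      } else {
        ens$spec$n_nodes
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, fitness = if (lev == "inf") "Inf" else "1",
        n_nodes = n_nodes, reps = reps,
        dispersion = ci$estimate, lower = ci$lower, upper = ci$upper,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Histogram of standardized takeover times with a fitted density
#'
#' Minimal base-graphics helper: plots the standardized sample histogram and
#' overlays a method-of-moments Gumbel and/or shifted-lognormal density.
#'
#' @param sample_set A `sample_set`.
#' @param fits Character vector among `"gumbel"`, `"shifted_lognormal"`.
#' @param breaks Passed to [graphics::hist()].
#' @return Invisibly, the list of `fit_result`s.
#' @export
plot_sample_set <- function(sample_set, fits = c("gumbel", "shifted_lognormal"),
                            breaks = 60) {
  stopifnot(inherits(sample_set, "sample_set"))
  z <- standardize(sample_set$times)
  graphics::hist(z,
    breaks = breaks, freq = FALSE, col = "grey90", border = "grey70",
    main = "Standardized takeover times", xlab = "standardized time"
  )
  xs <- seq(min(z), max(z), length.out = 400)
  cols <- c(gumbel = "blue", shifted_lognormal = "red")
  out <- list()
  for (f in fits) {
    fit <- if (f == "gumbel") fit_gumbel_moments(z) else fit_shifted_lognormal_moments(z)
    if (fit$converged) {
      graphics::lines(xs, fitted_density(fit, xs), col = cols[[f]], lwd = 2)
    }
    out[[f]] <- fit
  }
  invisible(out)
}
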