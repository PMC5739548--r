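#' Specify a Moran invasion simulation
#'
#' Bundles a network, an update rule, an invader fitness, an initial dose and
#' a takeover threshold into a validated specification for [run_trial()] and
#' [run_conditioned_ensemble()].
#'
#' Under the Birth-death (Bd) rule a node is chosen from the whole population
#' with probability proportional to its fitness and a uniform random neighbour
#' adopts its type; under Death-birth (Db) a node is chosen to die with
#' probability proportional to the inverse of its fitness and adopts the type
#' of a uniform random neighbour. Invaders have relative fitness `fitness`,
#' residents fitness 1. `fitness = Inf` is handled by a dedicated code path:
#' Bd births are uniform over invaders and Db deaths uniform over residents,
#' so the invader count never decreases.
#'
#' Time is counted in elementary update events, including events that change
#' nothing (an invader replacing an invader, or a resident a resident); this
#' is the convention under which waiting times between invader-count
#' increments are geometric random variables.
#'
#' @param network A [make_network()] object.
#' @param rule `"Bd"` (Birth-death) or `"Db"` (Death-birth).
#' @param fitness Positive invader fitness `r`, or `Inf`.
#' @param dose Initial number of invaders, placed on distinct uniform random
#'   nodes.
#' @param f Takeover fraction in (0, 1]: the trial succeeds when the invader
#'   count reaches `ceiling(f * N)`. Ignored when `threshold` is given.
#' @param threshold Explicit target invader count (overrides `f`).
#'
#' @return An object of class `"simulation_spec"`.
#' @examples
#' net <- make_network("complete", n = 50)
#' simulation_spec(net, "Bd", fitness = Inf)
#' @export
simulation_spec <- function(network, rule = c("Bd", "Db"), fitness = Inf,
                            dose = 1L, f = 1, threshold = NULL) {
  stopifnot(inherits(network, "moran_network"))
  rule <- match.arg(rule)
  if (length(fitness) != 1L || is.na(fitness) || fitness <= 0) {
    stop("'fitness' must be a single positive number (Inf allowed)", call. = FALSE)
  }
  n <- network$n_nodes
  if (is.null(threshold)) {
    if (length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
      stop("'f' must be in (0, 1]", call. = FALSE)
    }
    threshold <- as.integer(ceiling(f * n))
  }
  threshold <- as.integer(threshold)
  dose <- as.integer(dose)
  if (dose < 1L || dose >= threshold || threshold > n) {
    stop("need 1 <= dose < threshold <= number of nodes", call. = FALSE)
  }
  structure(
    list(
      network = network, rule = rule, fitness = fitness,
      dose = dose, threshold = threshold
    ),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %s on %s (N=%d), r=%s, dose=%d, threshold=%d\n",
    x$rule, x$network$family, x$network$n_nodes,
    if (is.infinite(x$fitness)) "Inf" else format(x$fitness),
    x$dose, x$threshold
  ))
  invisible(x)
}

rule_code <- function(rule) if (rule == "Db") 1L else 0L

#' Apply one elementary Moran update
#'
#' Advances a labelled network state by a single Bd or Db event. Absorbing
#' states (all-invader, all-resident) are legal inputs and are returned
#' unchanged under the infinite-fitness code path; at finite fitness the event
#' still happens but cannot change anything.
#'
#' @param labels Integer/logical vector over nodes; nonzero marks an invader.
#' @param network A [make_network()] object.
#' @inheritParams simulation_spec
#' @return Updated integer 0/1 label vector.
#' @export
moran_step <- function(labels, network, rule = c("Bd", "Db"), fitness = Inf) {
  stopifnot(inherits(network, "moran_network"))
  rule <- match.arg(rule)
  if (length(labels) != network$n_nodes) {
    stop("'labels' must have one entry per node", call. = FALSE)
  }
  flat <- flat_adjacency(network)
  cpp_one_step(
    flat$offsets, flat$neighbors, as.integer(labels != 0),
    rule_code(rule), if (is.infinite(fitness)) 1 else fitness,
    is.infinite(fitness)
  )
}

#' Run a single invasion trial
#'
#' Seeds `dose` invaders on distinct uniform random nodes and applies the
#' update rule until the invader count reaches the threshold
#' (`outcome = "reached_threshold"`) or zero (`outcome = "extinct"`).
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer seed.
#' @param max_steps Safety cap on elementary events per trial.
#' @return A list with `outcome` and `steps` (elementary events taken).
#' @examples
#' net <- make_network("complete", n = 20)
#' run_trial(simulation_spec(net, "Bd", fitness = Inf), seed = 1)
#' @export
run_trial <- function(spec, seed = NULL, max_steps = 1e12) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  flat <- flat_adjacency(spec$network)
  res <- cpp_run_trial(
    flat$offsets, flat$neighbors, rule_code(spec$rule),
    if (is.infinite(spec$fitness)) 1 else spec$fitness,
    is.infinite(spec$fitness), spec$dose, spec$threshold, max_steps
  )
  list(
    outcome = if (res[1] > 0) "reached_threshold" else "extinct",
    steps = res[2]
  )
}

new_sample_set <- function(times, spec, n_rejected = 0) {
  structure(
    list(times = as.numeric(times), spec = spec, n_rejected = n_rejected),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(
    "<sample_set> %d takeover times (n_rejected=%g), mean=%.4g, sd=%.4g\n",
    length(x$times), x$n_rejected, mean(x$times), stats::sd(x$times)
  ))
  invisible(x)
}

#' Sample takeover times conditioned on invader success
#'
#' Draws an ensemble of trials and keeps only those in which the invaders
#' reach the threshold; extinct trials are discarded by plain rejection and
#' counted in `n_rejected`. At infinite fitness no trial can go extinct, so
#' the ensemble is simply `n_samples` fixation times.
#'
#' @inheritParams run_trial
#' @param n_samples Number of conditioned takeover times to return.
#' @param max_attempts Safety cap on total trials; exceeding it signals an
#'   implausibly low fixation probability for the given spec.
#' @param fresh_network Optional function of no arguments returning a new
#'   [make_network()] object; when given, a fresh network is drawn for every
#'   trial (used for random graph families, where the ensemble then averages
#'   over the graph distribution as well).
#' @return A `sample_set`: list with `times`, `spec`, `n_rejected`.
#' @examples
#' net <- make_network("complete", n = 20)
#' spec <- simulation_spec(net, "Bd", fitness = Inf)
#' ens <- run_conditioned_ensemble(spec, 100, seed = 1)
#' mean(ens$times)
#' @export
run_conditioned_ensemble <- function(spec, n_samples, seed = NULL,
                                     max_attempts = 1000 * n_samples,
                                     max_steps = 1e12,
                                     fresh_network = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- if (is.infinite(spec$fitness)) 1 else spec$fitness
  r_inf <- is.infinite(spec$fitness)

  if (is.null(fresh_network)) {
    flat <- flat_adjacency(spec$network)
    res <- cpp_run_ensemble(
      flat$offsets, flat$neighbors, rule_code(spec$rule), r, r_inf,
      spec$dose, spec$threshold, as.integer(n_samples), max_attempts, max_steps
    )
    return(new_sample_set(res$times, spec, res$n_rejected))
  }

  times <- numeric(n_samples)
  got <- 0L
  attempts <- 0
  rejected <- 0
  while (got < n_samples) {
    if (attempts >= max_attempts) {
      stop("exceeded ", max_attempts, " attempts with only ", got, " of ",
        n_samples, " takeovers",
        call. = FALSE
      )
    }
    attempts <- attempts + 1
    net <- fresh_network()
    flat <- flat_adjacency(net)
    res <- cpp_run_trial(
      flat$offsets, flat$neighbors, rule_code(spec$rule), r, r_inf,
      spec$dose, min(spec$threshold, net$n_nodes), max_steps
    )
    if (res[1] > 0) {
      got <- got + 1L
      times[got] <- res[2]
    } else {
      rejected <- rejected + 1
    }
  }
  new_sample_set(times, spec, rejected)
}

#' Exact coupon-collector sampler for the complete graph at infinite fitness
#'
#' On the complete graph with an infinitely fit invader under Bd updates, the
#' waiting time to add a new invader when `m` are present is geometric with
#' success probability `(N - m) / (N - 1)`, so the fixation time is
#' `T = sum over k = 1..N-1 of Geo(k / (N - 1))` (each geometric supported on
#' 1, 2, ...) -- the coupon collector's waiting time over `N - 1` items. This
#' sampler draws `T` directly and is identical in distribution to per-step
#' simulation with [run_trial()].
#'
#' @param N Number of nodes (>= 2).
#' @param n_samples Number of fixation times to draw.
#' @param seed Optional integer seed.
#' @return A `sample_set`.
#' @examples
#' s <- sample_coupon_collector(150, 1000, seed = 1)
#' mean(s$times) # close to (N - 1) * H(N - 1)
#' @export
sample_coupon_collector <- function(N, n_samples, seed = NULL) {
  stopifnot(N >= 2, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  times <- rep(0, n_samples)
  for (k in seq_len(N - 1L)) {
    times <- times + stats::rgeom(n_samples, k / (N - 1)) + 1
  }
  spec <- list(
    family = "complete", n_nodes = N, rule = "Bd", fitness = Inf,
    dose = 1L, threshold = N, sampler = "coupon_collector"
  )
  new_sample_set(times, spec, 0)
}

#' Exact contiguous-block sampler for the 1D ring at infinite fitness
#'
#' On a periodic ring with an infinitely fit invader under Bd updates the
#' invader set stays a contiguous arc; with `m >= 2` invaders only the two
#' end invaders can grow the arc, each picking its outward resident neighbour
#' with probability 1/2, so the per-step growth probability is `1/m` (and 1
#' when `m = 1`). The fixation time is therefore
#' `T = Geo(1) + sum over m = 2..N-1 of Geo(1/m)`, identical in distribution
#' to per-step simulation.
#'
#' @inheritParams sample_coupon_collector
#' @return A `sample_set`.
#' @examples
#' s <- sample_ring_growth(75, 1000, seed = 1)
#' mean(s$times) # close to (N^2 - N) / 2
#' @export
sample_ring_growth <- function(N, n_samples, seed = NULL) {
  stopifnot(N >= 2, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  times <- rep(1, n_samples) # Geo(1) for the first growth step
  if (N > 2L) {
    for (m in 2:(N - 1L)) {
      times <- times + stats::rgeom(n_samples, 1 / m) + 1
    }
  }
  spec <- list(
    family = "ring_1d", n_nodes = N, rule = "Bd", fitness = Inf,
    dose = 1L, threshold = N, sampler = "ring_growth"
  )
  new_sample_set(times, spec, 0)
}
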