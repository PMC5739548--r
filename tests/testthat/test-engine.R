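# Per-step engine: single updates, trials, conditioning, fast samplers.

test_that("one-step growth frequencies match the complete-graph formulas", {
  set.seed(101)
  # N=3, m=1, r=1: P(grow) = [1*1/(1+2)] * [2/2] = 1/3
  net3 <- make_network("complete", n = 3)
  d <- step_deltas(c(1L, 0L, 0L), net3, "Bd", 1, 6000)
  phat <- mean(d == 1)
  expect_lt(abs(phat - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 6000))

  # finite r on a larger complete graph: p_m+ and p_m- as products of the
  # fitness-weighted birth choice and the uniform neighbour choice
  N <- 20; m <- 6; r <- 2
  net <- make_network("complete", n = N)
  labels <- c(rep(1L, m), rep(0L, N - m))
  p_up <- (m * r / (m * r + N - m)) * ((N - m) / (N - 1))
  p_dn <- ((N - m) / (m * r + N - m)) * (m / (N - 1))
  d <- step_deltas(labels, net, "Bd", r, 8000)
  expect_lt(abs(mean(d == 1) - p_up), 4 * sqrt(p_up * (1 - p_up) / 8000))
  expect_lt(abs(mean(d == -1) - p_dn), 4 * sqrt(p_dn * (1 - p_dn) / 8000))

  # r -> infinity: growth probability (N-m)/(N-1), shrink impossible
  p_inf <- (N - m) / (N - 1)
  d <- step_deltas(labels, net, "Bd", Inf, 8000)
  expect_true(all(d >= 0))
  expect_lt(abs(mean(d == 1) - p_inf), 4 * sqrt(p_inf * (1 - p_inf) / 8000))
})

test_that("Db one-step frequencies equal Bd's with the two stages exchanged", {
  set.seed(102)
  # complete graph, r=1: Db growth = P(resident dies) * P(neighbour invader)
  # = [(N-m)/N] * [m/(N-1)], the Bd product with the roles swapped; on a
  # complete graph at r=1 the two coincide. Checked for every m on N=4.
  net4 <- make_network("complete", n = 4)
  for (m in 1:3) {
    labels <- c(rep(1L, m), rep(0L, 4 - m))
    p_up_oracle <- ((4 - m) / 4) * (m / 3)
    d_db <- step_deltas(labels, net4, "Db", 1, 6000)
    d_bd <- step_deltas(labels, net4, "Bd", 1, 6000)
    tol <- 4 * sqrt(p_up_oracle * (1 - p_up_oracle) / 6000)
    expect_lt(abs(mean(d_db == 1) - p_up_oracle), tol)
    expect_lt(abs(mean(d_bd == 1) - p_up_oracle), tol)
  }
})

test_that("absorbing states are fixed points of both rules", {
  net <- make_network("ring_1d", n = 6)
  all_inv <- rep(1L, 6)
  all_res <- rep(0L, 6)
  set.seed(103)
  for (rule in c("Bd", "Db")) {
    for (fit in c(1, 5, Inf)) {
      expect_equal(moran_step(all_inv, net, rule, fit), all_inv)
      expect_equal(moran_step(all_res, net, rule, fit), all_res)
    }
  }
})

test_that("infinitely fit Db on a star converts one spoke per step from the hub", {
  # hub sole invader: every step a uniform spoke dies and copies its only
  # neighbour (the invader hub) with certainty
  net <- make_network("star", spokes = 10)
  labels <- c(1L, rep(0L, 10)) # node 1 is the hub
  set.seed(104)
  for (step in 1:10) {
    labels <- moran_step(labels, net, "Db", Inf)
    expect_equal(sum(labels), 1L + step)
  }
})

test_that("trials absorb correctly and count every elementary event", {
  # complete N=2, r=Inf, Bd: the single resident is replaced on step 1
  net2 <- make_network("complete", n = 2)
  set.seed(105)
  for (i in 1:5) {
    tr <- run_trial(simulation_spec(net2, "Bd", Inf))
    expect_equal(tr$outcome, "reached_threshold")
    expect_equal(tr$steps, 1)
  }

  # complete N=3, r=Inf, Bd: T = 1 + Geometric(1/2) (p1 = 1, p2 = 1/2),
  # so E[T] = 3; check the whole law against the geometric oracle
  net3 <- make_network("complete", n = 3)
  spec3 <- simulation_spec(net3, "Bd", Inf)
  t_sim <- vapply(1:4000, function(i) run_trial(spec3)$steps, numeric(1))
  t_oracle <- 1 + rgeom(4000, 0.5) + 1
  expect_lt(abs(mean(t_sim) - 3), 4 * sqrt(2) / sqrt(4000)) # Var T = 2
  expect_true(ks2_not_rejected(t_sim, t_oracle))

  # r=Inf monotonicity: no extinction under either rule, and every sample
  # needs at least threshold - dose steps
  net <- make_network("erdos_renyi", n = 20, p = 0.4, seed = 9)
  for (rule in c("Bd", "Db")) {
    ens <- run_conditioned_ensemble(simulation_spec(net, rule, Inf), 300)
    expect_equal(ens$n_rejected, 0)
    expect_true(all(ens$times >= 20 - 1))
  }
})

test_that("conditioned neutral ensembles accept at the fixation probability", {
  set.seed(106)
  # oracle: absorbing-Markov-chain solve on N=4 gives h(1) = 1/4
  h <- fixation_prob_complete_neutral(4)
  expect_equal(h, 1 / 4, tolerance = 1e-10)

  net4 <- make_network("complete", n = 4)
  ens <- run_conditioned_ensemble(simulation_spec(net4, "Bd", 1), 2000)
  attempts <- 2000 + ens$n_rejected
  phat <- 2000 / attempts
  expect_lt(abs(phat - h), 4 * sqrt(h * (1 - h) / attempts))

  # conditioned times on a larger graph are right-skewed
  net50 <- make_network("complete", n = 50)
  ens50 <- run_conditioned_ensemble(simulation_spec(net50, "Bd", 1), 1500)
  expect_gt(sample_skewness(ens50$times), 0)
})

test_that("fast geometric-sum samplers match the per-step engine in law", {
  set.seed(107)
  # complete graph, small N: coupon-collector sampler vs engine
  n_cc <- 3000
  cc <- sample_coupon_collector(25, n_cc)
  net <- make_network("complete", n = 25)
  spec <- simulation_spec(net, "Bd", Inf)
  t_engine <- run_conditioned_ensemble(spec, n_cc)$times
  expect_true(ks2_not_rejected(cc$times, t_engine))
  mo <- fixation_moments("complete", 25)
  expect_lt(abs(mean(cc$times) - mo$mean), 3 * sqrt(mo$var / n_cc))

  # ring sampler vs engine
  ring <- sample_ring_growth(20, n_cc)
  netr <- make_network("ring_1d", n = 20)
  t_ring <- run_conditioned_ensemble(simulation_spec(netr, "Bd", Inf), n_cc)$times
  expect_true(ks2_not_rejected(ring$times, t_ring))
  mor <- fixation_moments("ring_1d", 20)
  expect_equal(mor$mean, (20^2 - 20) / 2)
  expect_lt(abs(mean(ring$times) - mor$mean), 3 * sqrt(mor$var / n_cc))

  # N=2 and N=3 degenerate cases
  expect_true(all(sample_coupon_collector(2, 50)$times == 1))
  s3 <- sample_ring_growth(3, 2000)
  c3 <- sample_coupon_collector(3, 2000) # ring and complete coincide at N=3
  expect_true(ks2_not_rejected(s3$times, c3$times))
})

test_that("Bd and Db fixation times coincide on the complete graph at r=Inf", {
  set.seed(108)
  net <- make_network("complete", n = 40)
  bd <- run_conditioned_ensemble(simulation_spec(net, "Bd", Inf), 3000)
  db <- run_conditioned_ensemble(simulation_spec(net, "Db", Inf), 3000)
  expect_true(ks2_not_rejected(bd$times, db$times))
})

test_that("ensembles are reproducible from seed and specs validate", {
  net <- make_network("complete", n = 15)
  spec <- simulation_spec(net, "Bd", 2)
  a <- run_conditioned_ensemble(spec, 200, seed = 42)
  b <- run_conditioned_ensemble(spec, 200, seed = 42)
  expect_identical(a$times, b$times)
  expect_identical(a$n_rejected, b$n_rejected)

  expect_error(simulation_spec(net, "Bd", -1), "positive")
  expect_error(simulation_spec(net, "Bd", 1, dose = 15), "dose")
  expect_error(simulation_spec(net, "Bd", 1, f = 0), "f")
  expect_error(simulation_spec(net, "Bd", 1, dose = 3, threshold = 3), "dose")
})
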