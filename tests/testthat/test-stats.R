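# Dispersion factor, standardization, moment fits, KS distance, CSV/JSON IO.

test_that("dispersion factor matches hand-computed geometric statistics", {
  s <- dispersion_factor(c(1, exp(2)))
  expect_equal(s$geo_mean, exp(1))
  expect_equal(s$dispersion, exp(sqrt(2)))

  # constant sample: geometric mean c, dispersion exactly 1
  s2 <- dispersion_factor(rep(7, 10))
  expect_equal(s2$geo_mean, 7)
  expect_equal(s2$dispersion, 1)

  # scale invariance of sigma_G, and dimensionful mu_G scales linearly
  set.seed(301)
  x <- rlnorm(500, 2, 0.4)
  a <- dispersion_factor(x)
  b <- dispersion_factor(1000 * x)
  expect_equal(a$dispersion, b$dispersion)
  expect_equal(b$geo_mean, 1000 * a$geo_mean)

  expect_error(dispersion_factor(c(1, -2)), "positive")
  expect_error(dispersion_factor(3), "at least 2")

  # lognormal(sigma_log) recovery: dispersion -> exp(sigma_log)
  y <- rlnorm(1e5, meanlog = 1, sdlog = 0.35)
  expect_lt(abs(dispersion_factor(y)$dispersion - exp(0.35)) / exp(0.35), 0.01)
})

test_that("standardization is exact, idempotent and skew-preserving", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(302)
  x <- rexp(200)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  expect_equal(sample_skewness(z), sample_skewness(x))
  expect_equal(sample_skewness(z), sample_skewness(5 + 3 * x))
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("method-of-moments Gumbel fit inverts the standard moments", {
  # a sample with sd pi/sqrt(6) and mean gamma fits to (alpha, beta) ~ (0, 1)
  x <- c(-1, 1) * pi / sqrt(6) / sqrt(2) + euler_gamma()
  fit <- fit_gumbel_moments(x)
  expect_equal(unname(fit$params["beta"]), 1)
  expect_equal(unname(fit$params["alpha"]), 0)

  # parameter recovery on 1e5 draws from Gumbel(-gamma, 1)
  set.seed(303)
  g <- rgumbel(1e5, -euler_gamma(), 1)
  fit2 <- fit_gumbel_moments(g)
  expect_lt(abs(fit2$params["alpha"] + euler_gamma()), 0.02)
  expect_lt(abs(fit2$params["beta"] - 1), 0.02)

  # fitted density tracks the histogram of standardized coupon-collector
  # samples (sup error of the fitted density against the binned empirical
  # density after standardization)
  s <- sample_coupon_collector(150, 2e4)
  z <- standardize(s$times)
  fitz <- fit_gumbel_moments(z)
  h <- hist(z, breaks = 40, plot = FALSE)
  emp <- h$density
  fitted <- fitted_density(fitz, h$mids)
  expect_lt(max(abs(emp - fitted)), 0.05)
})

test_that("shifted-lognormal moment fit recovers planted parameters", {
  set.seed(304)
  x <- 5 + rlnorm(1e5, meanlog = 1.2, sdlog = 0.4)
  fit <- fit_shifted_lognormal_moments(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$params["shift"] - 5) / 5, 0.05)
  expect_lt(abs(fit$params["log_sd"] - 0.4) / 0.4, 0.05)
  expect_lt(abs(fit$params["log_mean"] - 1.2) / 1.2, 0.05)

  # the fitted law's skewness equals the sample skewness by construction
  w <- exp(fit$params[["log_sd"]]^2)
  skew_fit <- (w + 2) * sqrt(w - 1)
  expect_lt(abs(skew_fit - sample_skewness(x)), 1e-8)

  # symmetric input has no lognormal solution
  fit0 <- fit_shifted_lognormal_moments(c(-1, 0, 1))
  expect_false(fit0$converged)
})

test_that("KS distance behaves like a sup-norm statistic", {
  # single point at the reference median -> distance exactly 0.5
  expect_equal(ks_distance(0, stats::pnorm), 0.5)
  set.seed(305)
  for (n in c(100, 2000)) {
    d <- ks_distance(stats::rnorm(n), stats::pnorm)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_lt(d, 1.63 / sqrt(n)) # DKW-style 99th-percentile bound
  }
  # gumbel_cdf is the matching distribution function for gumbel_density
  set.seed(306)
  g <- rgumbel(2000, 3, 2)
  expect_lt(ks_distance(g, function(x) gumbel_cdf(x, 3, 2)), 1.63 / sqrt(2000))
})

test_that("times CSV and sample-set JSON sidecars round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time", "3", "5", "8.5"), path)
  expect_equal(read_incubation_times(path), c(3, 5, 8.5))
  writeLines(c("2", "4"), path)
  expect_equal(read_incubation_times(path), c(2, 4))
  writeLines(c("time", "3", "oops"), path)
  expect_error(read_incubation_times(path), "non-numeric")

  set.seed(307)
  net <- make_network("complete", n = 10)
  ens <- run_conditioned_ensemble(simulation_spec(net, "Bd", 2), 50)
  out <- withr::local_tempfile(fileext = ".csv")
  write_sample_set(ens, out)
  back <- read_sample_set(out)
  expect_equal(back$times, ens$times)
  expect_equal(back$spec$family, "complete")
  expect_equal(back$spec$rule, "Bd")
  expect_equal(back$n_rejected, ens$n_rejected)
})

test_that("bootstrap CI covers the dispersion of a known lognormal", {
  set.seed(308)
  x <- rlnorm(3000, 0, 0.3)
  ci <- bootstrap_ci(x, n_boot = 400)
  expect_lt(ci$lower, exp(0.3))
  expect_gt(ci$upper, exp(0.3))
  expect_lt(ci$upper - ci$lower, 0.1)
})
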