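#' Dispersion factor (geometric standard deviation) and summary statistics
#'
#' The dispersion factor of a positive sample is its geometric standard
#' deviation `sigma_G = exp(sqrt(sum(log(x/mu_G)^2) / (n - 1)))`, with
#' `mu_G = exp(mean(log x))` the geometric mean. `log(sigma_G)` is the
#' maximum-likelihood scale of an unshifted lognormal, and `sigma_G` is the
#' dimensionless quantity Sartwell used to characterize incubation-period
#' variability (about 1.1-1.5 across many infectious diseases).
#'
#' @param times Positive numeric sample, `n >= 2`.
#' @return A `summary_stats` object: list with `n`, `mean`, `sd`, `skewness`,
#'   `geo_mean` and `dispersion` (`sigma_G >= 1`).
#' @examples
#' dispersion_factor(c(1, exp(2)))$dispersion # exp(sqrt(2))
#' @export
dispersion_factor <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all values must be finite and positive", call. = FALSE)
  }
  lx <- log(times)
  mu_g <- exp(mean(lx))
  sigma_g <- exp(sqrt(sum((lx - mean(lx))^2) / (length(lx) - 1)))
  s <- stats::sd(times)
  structure(
    list(
      n = length(times), mean = mean(times), sd = s,
      skewness = if (s > 0) sample_skewness(times) else NA_real_,
      geo_mean = mu_g, dispersion = sigma_g
    ),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> n=%d  mean=%.6g  sd=%.6g  skew=%.4f  geo_mean=%.6g  dispersion=%.4f\n",
    x$n, x$mean, x$sd, x$skewness, x$geo_mean, x$dispersion
  ))
  invisible(x)
}

#' Moment estimator of sample skewness
#'
#' `m3 / m2^(3/2)` with central moments using the 1/n convention
#' (bias-uncorrected).
#'
#' @param x Numeric sample, `n >= 2`, non-constant.
#' @return Sample skewness.
#' @export
sample_skewness <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) stop("skewness undefined for a constant sample", call. = FALSE)
  mean(d^3) / m2^1.5
}

#' Standardize a sample to zero mean and unit variance
#'
#' Uses the n-1 denominator for the standard deviation, so the output has
#' sample mean 0 and sample sd (n-1 convention) exactly 1. Skewness is
#' unchanged (affine invariance).
#'
#' @param times Numeric sample, `n >= 2`, non-constant.
#' @return Standardized numeric vector.
#' @examples
#' standardize(c(1, 2, 3)) # -1 0 1
#' @export
standardize <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(times)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant sample", call. = FALSE)
  (times - mean(times)) / s
}

#' Method-of-moments Gumbel fit
#'
#' Matches the first two moments: a Gumbel(alpha, beta) has mean
#' `alpha + beta * gamma` and variance `beta^2 pi^2 / 6`, so
#' `beta = sd * sqrt(6) / pi` and `alpha = mean - beta * gamma`.
#'
#' @param times Numeric sample, `n >= 2`, non-constant.
#' @return A `fit_result` with `family = "gumbel"`, `params = c(alpha, beta)`
#'   and `converged = TRUE`.
#' @examples
#' fit_gumbel_moments(c(-1, 0, 1, 2))
#' @export
fit_gumbel_moments <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(times)
  if (!is.finite(s) || s == 0) stop("degenerate (constant) sample", call. = FALSE)
  beta <- s * sqrt(6) / pi
  alpha <- mean(times) - beta * euler_gamma()
  new_fit_result("gumbel", c(alpha = alpha, beta = beta), TRUE)
}

#' Method-of-moments shifted (noncentral) lognormal fit
#'
#' Fits the three-parameter lognormal `shift + exp(Normal(log_mean, log_sd))`
#' by matching sample mean, variance and skewness. Writing
#' `w = exp(log_sd^2)`, the skewness of a lognormal is
#' `(w + 2) * sqrt(w - 1)`, a strictly increasing function of `w`; with
#' `u = sqrt(w - 1)` the matching equation becomes the depressed cubic
#' `u^3 + 3u - skew = 0`, whose unique real root is taken in closed form.
#' `log_sd`, `log_mean` and `shift` then follow from the variance and mean.
#' Only right-skewed samples admit a fit; otherwise `converged = FALSE`.
#'
#' @param times Numeric sample, `n >= 3`, non-constant.
#' @return A `fit_result` with `family = "shifted_lognormal"`,
#'   `params = c(shift, log_mean, log_sd)` and a `converged` flag.
#' @examples
#' x <- 5 + exp(rnorm(1000, 1, 0.4))
#' fit_shifted_lognormal_moments(x)
#' @export
fit_shifted_lognormal_moments <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 3L) stop("need at least 3 values", call. = FALSE)
  m <- mean(times)
  v <- stats::var(times)
  if (!is.finite(v) || v == 0) stop("degenerate (constant) sample", call. = FALSE)
  g1 <- sample_skewness(times)
  if (g1 <= 0) {
    return(new_fit_result(
      "shifted_lognormal",
      c(shift = NA_real_, log_mean = NA_real_, log_sd = NA_real_),
      FALSE
    ))
  }
  # unique real root of u^3 + 3u - g1 = 0 (Cardano; discriminant > 0)
  h <- sqrt(g1^2 / 4 + 1)
  u <- cbrt(g1 / 2 + h) + cbrt(g1 / 2 - h)
  w <- 1 + u^2 # exp(log_sd^2)
  log_sd <- sqrt(log(w))
  log_mean <- 0.5 * log(v / (w * (w - 1)))
  shift <- m - exp(log_mean + log_sd^2 / 2)
  new_fit_result(
    "shifted_lognormal",
    c(shift = shift, log_mean = log_mean, log_sd = log_sd), TRUE
  )
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

new_fit_result <- function(family, params, converged) {
  structure(
    list(family = family, params = params, converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s (%s): %s\n",
    x$family, if (x$converged) "converged" else "no valid fit",
    paste(names(x$params), signif(x$params, 6), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Density of a fitted distribution
#'
#' @param fit A `fit_result` from [fit_gumbel_moments()] or
#'   [fit_shifted_lognormal_moments()].
#' @param x Evaluation points.
#' @return Density values.
#' @export
fitted_density <- function(fit, x) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("fit did not converge; no density available", call. = FALSE)
  p <- fit$params
  switch(fit$family,
    gumbel = gumbel_density(x, p[["alpha"]], p[["beta"]]),
    shifted_lognormal = {
      d <- numeric(length(x))
      ok <- x > p[["shift"]]
      d[ok] <- stats::dlnorm(x[ok] - p[["shift"]], p[["log_mean"]], p[["log_sd"]])
      d
    },
    stop("unknown fit family: ", fit$family, call. = FALSE)
  )
}

#' Kolmogorov-Smirnov distance to a reference distribution
#'
#' Supremum distance between the empirical CDF of a sample and a reference
#' CDF. For a sample from the reference itself this is below
#' `1.63 / sqrt(n)` with probability 99% (Kolmogorov asymptotics), which is
#' how the simulators are validated against their limit laws.
#'
#' @param times Numeric sample.
#' @param reference_cdf Vectorized CDF function.
#' @return KS distance in `[0, 1]`.
#' @examples
#' ks_distance(qnorm(ppoints(100)), pnorm)
#' @export
ks_distance <- function(times, reference_cdf) {
  x <- sort(as.numeric(times))
  n <- length(x)
  if (n < 1L) stop("need at least 1 value", call. = FALSE)
  fx <- reference_cdf(x)
  max(abs(seq_len(n) / n - fx), abs((seq_len(n) - 1) / n - fx))
}

#' Critical value of the (one- or two-sample) KS statistic
#'
#' Asymptotic Kolmogorov critical value `c(alpha) = sqrt(-log(alpha/2)/2)`,
#' scaled by `sqrt(1/n)` (one sample) or `sqrt((n + m)/(n m))` (two samples).
#'
#' @param alpha Significance level.
#' @param n,m Sample sizes (`m = Inf` for a one-sample test).
#' @return Critical KS distance.
#' @export
ks_critical <- function(alpha, n, m = Inf) {
  c_a <- sqrt(-log(alpha / 2) / 2)
  if (is.infinite(m)) c_a / sqrt(n) else c_a * sqrt((n + m) / (n * m))
}

#' Bootstrap confidence interval for a sample statistic
#'
#' Nonparametric percentile bootstrap, used for the confidence intervals on
#' dispersion factors and skewness.
#'
#' @param times Numeric sample.
#' @param statistic Function mapping a sample to a single number. Defaults to
#'   the dispersion factor.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @return List with `estimate`, `lower`, `upper`, `conf`, `n_boot`.
#' @examples
#' bootstrap_ci(rlnorm(500, 0, 0.3), n_boot = 200)
#' @export
bootstrap_ci <- function(times, statistic = function(x) dispersion_factor(x)$dispersion,
                         n_boot = 2000L, conf = 0.95) {
  times <- as.numeric(times)
  n <- length(times)
  est <- statistic(times)
  boot <- vapply(
    seq_len(n_boot),
    function(i) statistic(times[sample.int(n, n, replace = TRUE)]),
    numeric(1)
  )
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], conf = conf, n_boot = n_boot)
}
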