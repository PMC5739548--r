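#' Gumbel probability density
#'
#' Density of a Gumbel(alpha, beta) random variable,
#' `h(x) = beta^-1 exp(-(x - alpha)/beta) exp(-exp(-(x - alpha)/beta))`.
#' The standardized limit laws of takeover times on the complete and star
#' graphs are Gumbel(-gamma, 1), gamma the Euler-Mascheroni constant, which
#' has mean 0 and variance pi^2/6.
#'
#' @param x Numeric vector of evaluation points.
#' @param alpha Location parameter.
#' @param beta Scale parameter (> 0).
#' @return Density values, same length as `x`.
#' @examples
#' gumbel_density(0, 0, 1) # 1/e
#' @export
gumbel_density <- function(x, alpha = -euler_gamma(), beta = 1) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("'beta' must be a single positive number", call. = FALSE)
  }
  z <- (x - alpha) / beta
  exp(-z - exp(-z)) / beta
}

#' Gumbel cumulative distribution function
#'
#' @inheritParams gumbel_density
#' @return CDF values `exp(-exp(-(x - alpha)/beta))`.
#' @export
gumbel_cdf <- function(x, alpha = -euler_gamma(), beta = 1) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("'beta' must be a single positive number", call. = FALSE)
  }
  exp(-exp(-(x - alpha) / beta))
}

#' Euler-Mascheroni constant
#'
#' @return gamma = 0.5772156649...
#' @export
euler_gamma <- function() 0.577215664901532860606512

#' Asymptotic law of the takeover time on a solvable network
#'
#' Returns the centering and scaling under which the fixation time `T` of an
#' infinitely fit Bd invader converges in distribution, together with the
#' limiting family:
#'
#' * complete graph: `(T - mu_N) / N -> Gumbel(-gamma, 1)` with
#'   `mu_N = (N - 1) H(N - 1)` (the exact finite-N coupon-collector mean;
#'   `mu_N` is asymptotically `N log N + N gamma`);
#' * star with `N` spokes: `(T - N^2 log N - (gamma - 1) N^2) / N^2
#'   -> Gumbel(-gamma, 1)`;
#' * 1D ring: `(T - (N^2 - N)/2) / sqrt((2N^3 - 3N^2 + N)/6) -> Normal(0,1)`.
#'
#' The exact harmonic sum is used for the complete-graph centering because it
#' gives markedly better agreement at moderate N; set `exact = FALSE` for the
#' asymptotic form. 2D/3D lattices and the random families have no closed-form
#' centering here and are standardized empirically instead.
#'
#' @param family `"complete"`, `"star"` or `"ring_1d"`.
#' @param N Number of nodes; for `"star"`, the number of spokes.
#' @param exact Use the exact finite-N centering where available.
#' @return A `limit_law` object: list with `family` (`"gumbel"` or
#'   `"normal"`), `location`, `scale` and, for Gumbel, `shape = c(alpha, beta)
#'   = c(-gamma, 1)` for the standardized variable.
#' @examples
#' limit_law("ring_1d", 75)$location # 2775
#' @export
limit_law <- function(family, N, exact = TRUE) {
  family <- match.arg(family, c("complete", "star", "ring_1d"))
  stopifnot(length(N) == 1L, N >= 2, N == round(N))
  g <- euler_gamma()
  switch(family,
    complete = {
      loc <- if (exact) (N - 1) * sum(1 / seq_len(N - 1)) else N * log(N) + N * g
      new_limit_law("gumbel", loc, N)
    },
    star = {
      new_limit_law("gumbel", N^2 * log(N) + (g - 1) * N^2, N^2)
    },
    ring_1d = {
      new_limit_law("normal", (N^2 - N) / 2, sqrt((2 * N^3 - 3 * N^2 + N) / 6))
    }
  )
}

new_limit_law <- function(family, location, scale) {
  structure(
    list(
      family = family, location = location, scale = scale,
      shape = if (family == "gumbel") c(alpha = -euler_gamma(), beta = 1)
    ),
    class = "limit_law"
  )
}

#' @export
print.limit_law <- function(x, ...) {
  cat(sprintf(
    "<limit_law> %s: location %.6g, scale %.6g\n",
    x$family, x$location, x$scale
  ))
  invisible(x)
}

#' Standardize takeover times by a limit law
#'
#' @param times Numeric vector of takeover times.
#' @param law A [limit_law()] object.
#' @return `(times - location) / scale`.
#' @export
standardize_by_law <- function(times, law) {
  stopifnot(inherits(law, "limit_law"))
  (times - law$location) / law$scale
}

#' Exact finite-N moments of solvable fixation-time laws
#'
#' Mean and variance of the geometric-sum representation of the fixation time
#' at infinite fitness: complete graph `T = sum Geo(k/(N-1))`, ring
#' `T = Geo(1) + sum Geo(1/m)`.
#'
#' @inheritParams limit_law
#' @return List with `mean` and `var`.
#' @export
fixation_moments <- function(family, N) {
  family <- match.arg(family, c("complete", "ring_1d"))
  stopifnot(N >= 2, N == round(N))
  if (family == "complete") {
    p <- seq_len(N - 1) / (N - 1)
    list(mean = sum(1 / p), var = sum((1 - p) / p^2))
  } else {
    m <- seq_len(N - 1)[-1] # 2..N-1; the first step is Geo(1), variance 0
    list(mean = 1 + sum(m), var = sum((1 - 1 / m) * m^2))
  }
}

#' Asymptotic skewness of fixation times on lattices of dimension d >= 3
#'
#' For a d-dimensional periodic lattice (d >= 3) the fixation-time
#' distribution of an infinitely fit Bd invader is right-skewed with
#' asymptotic skewness `2 zeta(3 eta) / zeta(2 eta)^(3/2)`, `eta = 1 - 1/d`,
#' `zeta` the Riemann zeta function. The skew increases monotonically with
#' dimension and approaches the Gumbel skewness `12 sqrt(6) zeta(3) / pi^3`
#' as d grows; 1D and 2D lattices are asymptotically normal (zero skew), so
#' d = 2 is the critical dimension.
#'
#' @param d Lattice dimension, integer >= 3.
#' @return The asymptotic skewness (positive).
#' @examples
#' lattice_skew(3)
#' @export
lattice_skew <- function(d) {
  if (length(d) != 1L || !is.finite(d) || d != round(d) || d < 3) {
    stop("'d' must be an integer >= 3; 1D and 2D lattices are asymptotically normal",
      call. = FALSE
    )
  }
  eta <- 1 - 1 / d
  2 * pracma::zeta(3 * eta) / pracma::zeta(2 * eta)^1.5
}

#' Skewness of the Gumbel distribution
#'
#' @return `12 * sqrt(6) * zeta(3) / pi^3` = 1.1395...
#' @export
gumbel_skewness <- function() 12 * sqrt(6) * pracma::zeta(3) / pi^3

#' Deterministic exponential-growth incubation time
#'
#' The classical heterogeneity explanation of lognormal incubation periods:
#' a pathogen grows exponentially from inoculum `N0` at rate `r`,
#' `N(t) = N0 exp(r t)`, and symptoms appear when `N` reaches threshold
#' `theta`, giving `T = (log theta - log N0) / r`. If `theta` (or `N0`) is
#' normally distributed across hosts, `T` is (shifted) lognormally
#' distributed; without randomness this model predicts a single deterministic
#' incubation period.
#'
#' @param rate Exponential growth rate `r` (> 0). Vectorized.
#' @param threshold Symptom threshold population `theta` (> `inoculum`).
#' @param inoculum Initial population `N0` (> 0).
#' @return Incubation time(s) `T`.
#' @examples
#' deterministic_incubation(1, exp(1) * 10, 10) # exactly 1
#' @export
deterministic_incubation <- function(rate, threshold, inoculum) {
  if (any(rate <= 0)) stop("'rate' must be positive", call. = FALSE)
  if (any(inoculum <= 0)) stop("'inoculum' must be positive", call. = FALSE)
  if (any(threshold <= inoculum)) {
    stop("'threshold' must exceed 'inoculum' (otherwise incubation is not positive)",
      call. = FALSE
    )
  }
  (log(threshold) - log(inoculum)) / rate
}
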