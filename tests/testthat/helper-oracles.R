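# Shared oracles and small helpers for the test suite. These stay independent
# of the code paths they validate: probabilities come from hand formulas or
# linear algebra, zeta values from Euler-Maclaurin summation, Gumbel moments
# from quadrature.

# Fixation probability of m0 neutral invaders on the complete graph of N
# nodes, by solving the absorbing-Markov-chain linear system for the embedded
# invader-count walk (self-loops drop out of the hitting probabilities).
fixation_prob_complete_neutral <- function(N, m0 = 1L) {
  # h[m] = P(hit N before 0 | m invaders); h0 = 0, hN = 1; at r = 1 the
  # embedded walk is symmetric, but solve the system rather than assume it.
  up <- function(m) (m / N) * ((N - m) / (N - 1))
  down <- function(m) ((N - m) / N) * (m / (N - 1))
  A <- matrix(0, N - 1, N - 1)
  b <- numeric(N - 1)
  for (m in 1:(N - 1)) {
    pu <- up(m); pd <- down(m); tot <- pu + pd
    A[m, m] <- 1
    if (m > 1) A[m, m - 1] <- -pd / tot
    if (m < N - 1) A[m, m + 1] <- -pu / tot
    if (m == N - 1) b[m] <- pu / tot
  }
  solve(A, b)[m0]
}

# Riemann zeta via Euler-Maclaurin (independent of pracma): sum to K, then
# tail integral and correction terms; ~1e-12 accurate for s > 1 at K = 200.
zeta_em <- function(s, K = 200) {
  n <- seq_len(K)
  sum(n^(-s)) + K^(1 - s) / (s - 1) - 0.5 * K^(-s) +
    s * K^(-s - 1) / 12 - s * (s + 1) * (s + 2) * K^(-s - 3) / 720
}

# Central moments of the Gumbel(alpha, beta) density by quadrature.
gumbel_moment_quad <- function(k, alpha = 0, beta = 1, central = TRUE) {
  mu <- if (central) {
    stats::integrate(function(x) x * gumbel_density(x, alpha, beta),
      alpha - 20 * beta, alpha + 60 * beta,
      rel.tol = 1e-12
    )$value
  } else {
    0
  }
  stats::integrate(function(x) (x - mu)^k * gumbel_density(x, alpha, beta),
    alpha - 20 * beta, alpha + 60 * beta,
    rel.tol = 1e-12, subdivisions = 400L
  )$value
}

# Two-sample KS check at level alpha via the asymptotic critical value.
ks2_not_rejected <- function(x, y, alpha = 0.01) {
  d <- suppressWarnings(stats::ks.test(x, y)$statistic)
  unname(d) < ks_critical(alpha, length(x), length(y))
}

# Gumbel(alpha, beta) sampler by inversion (for parameter-recovery tests).
rgumbel <- function(n, alpha, beta) alpha - beta * log(-log(stats::runif(n)))

# Monte-Carlo estimate of one-step invader-count transition frequencies from
# a fixed labelling.
step_deltas <- function(labels, network, rule, fitness, n_steps) {
  m0 <- sum(labels)
  vapply(seq_len(n_steps), function(i) {
    sum(moran_step(labels, network, rule, fitness)) - m0
  }, numeric(1))
}
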