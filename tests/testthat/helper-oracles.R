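# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the brute-force fitter grids the nonlinear
# parameters with an inner linear least squares, and the ARI oracle counts
# object pairs directly instead of building a contingency table.

# Minimal residual sum of squares of the damped-sinusoid-plus-trend family
# over a grid of (alpha, omega) with (a, b, c, d) profiled out linearly.
brute_force_s1 <- function(x, delta = 1,
                           alphas = seq(-0.3, 0.1, length.out = 41),
                           omegas = seq(0.1, 2, length.out = 96)) {
  m <- length(x)
  t <- seq_len(m) * delta
  best <- Inf
  for (al in alphas) {
    env <- exp(al * t)
    for (om in omegas) {
      X <- cbind(env * cos(om * t), env * sin(om * t), t, 1)
      r <- sum(qr.resid(qr(X), x)^2)
      if (r < best) best <- r
    }
  }
  best
}

# Hubert-Arabie ARI via direct pair counting: classify every object pair
# as together/apart in each partition and use the pair-count identity
# ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)).
pair_count_ari <- function(u, v) {
  n <- length(u)
  ut <- outer(u, u, "==")[upper.tri(diag(n))]
  vt <- outer(v, v, "==")[upper.tri(diag(n))]
  a <- sum(ut & vt)
  b <- sum(ut & !vt)
  c <- sum(!ut & vt)
  d <- sum(!ut & !vt)
  den <- (a + b) * (b + d) + (a + c) * (c + d)
  if (den == 0) return(1)
  2 * (a * d - b * c) / den
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (k in seq_len(next_max + 1)) {
      grow(c(labels, k), max(next_max, k))
    }
  }
  grow(integer(0), 0L)
  out
}

# Noise-free profile from explicit arithmetic (not evaluate_model).
direct_curve <- function(alpha, omega, a, b, c, d, m, delta = 1) {
  vapply(seq_len(m) * delta, function(t) {
    exp(alpha * t) * (a * cos(omega * t) + b * sin(omega * t)) + c * t + d
  }, numeric(1))
}
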