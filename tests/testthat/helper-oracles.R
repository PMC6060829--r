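# Independent numerical oracles used across the suite.

# CDF of a circular density by trapezoid quadrature on a fine grid,
# independent of the package's samplers.
quad_cdf <- function(spec, npts = 20001) {
  th <- seq(0, 2 * pi, length.out = npts)
  f <- dcirc(th, spec)
  dx <- th[2] - th[1]
  cdf <- c(0, cumsum((f[-1] + f[-npts]) / 2 * dx))
  list(theta = th, cdf = cdf / cdf[npts])  # normalise away quadrature residue
}

# Kolmogorov distance between the empirical CDF of x and a quadrature CDF
ks_distance <- function(x, oracle) {
  x <- sort(as.numeric(x))
  n <- length(x)
  Fx <- stats::approx(oracle$theta, oracle$cdf, xout = x)$y
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# brute-force Kuiper statistic straight from the definition
kuiper_brute <- function(x) {
  u <- sort(as.numeric(x) %% (2 * pi)) / (2 * pi)
  n <- length(u)
  dp <- -Inf; dm <- -Inf
  for (i in seq_len(n)) {
    dp <- max(dp, i / n - u[i])
    dm <- max(dm, u[i] - (i - 1) / n)
  }
  dp + dm
}

# brute-force Rao spacing statistic
rao_brute <- function(x) {
  s <- sort(as.numeric(x) %% (2 * pi))
  n <- length(s)
  gaps <- c(diff(s), 2 * pi - s[n] + s[1])
  0.5 * sum(abs(gaps - 2 * pi / n))
}

# circular mean helper for oracle-side checks
circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)

# smallest signed circular difference a - b, in (-pi, pi]
circ_diff <- function(a, b) (a - b + pi) %% (2 * pi) - pi
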