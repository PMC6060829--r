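# Vectorised test statistics on a matrix of samples (rows = samples, columns
# = observations, radians). The Monte-Carlo power engine and the null
# calibration both run through these, so a single-sample test and a 10,000-rep
# sweep use byte-identical statistic code.

stat_batch <- function(test, m, mu0 = 0, max_dim = 10L) {
  switch(test,
    rayleigh = {
      C <- rowMeans(cos(m)); S <- rowMeans(sin(m))
      sqrt(C^2 + S^2)
    },
    v = rowMeans(cos(m - mu0)),   # r * cos(thetabar - mu0) = mean cos(theta_i - mu0)
    kuiper = kuiper_stat_m(m),
    watson = watson_stat_m(m),
    rao = rao_stat_m(m),
    hermans_rasson = hr_stat_m(m),
    bogdan = bogdan_stat_m(m, max_dim)$stat,
    stop("unknown test: ", test, call. = FALSE)
  )
}

sorted_rows <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, sort.int, method = "quick"))
}

kuiper_stat_m <- function(m) {
  n <- ncol(m)
  u <- sorted_rows(m) / (2 * pi)
  i <- seq_len(n)
  dplus <- apply(sweep(-u, 2L, i / n, "+"), 1L, max)        # max_i (i/n - u_i)
  dminus <- apply(sweep(u, 2L, (i - 1) / n, "-"), 1L, max)  # max_i (u_i - (i-1)/n)
  dplus + dminus
}

watson_stat_m <- function(m) {
  n <- ncol(m)
  u <- sorted_rows(m) / (2 * pi)
  ubar <- rowMeans(u)
  ci <- (2 * seq_len(n) - 1) / (2 * n)
  # U2 = sum((u_i - ci)^2) - n*(ubar - 1/2)^2 + 1/(12n)
  rowSums(sweep(u, 2L, ci, "-")^2) - n * (ubar - 0.5)^2 + 1 / (12 * n)
}

rao_stat_m <- function(m) {
  n <- ncol(m)
  s <- sorted_rows(m)
  gaps <- cbind(s[, -1L, drop = FALSE] - s[, -n, drop = FALSE],
                2 * pi - s[, n] + s[, 1L])
  0.5 * rowSums(abs(gaps - 2 * pi / n))
}

# Hermans-Rasson kernel: circular distance drives the odd harmonics,
# |sin| the even ones; 2.895 balances the two. Centring constants make the
# kernel mean-zero under uniformity (they cancel in the Monte-Carlo p).
HR_BETA <- 2.895

hr_stat_one <- function(x) {
  d <- outer(x, x, "-")
  ad <- abs(d)
  cd <- pmin(ad, 2 * pi - ad)
  (sum(pi / 2 - cd) + HR_BETA * sum(2 / pi - abs(sin(d)))) / length(x)
}

hr_stat_m <- function(m) {
  apply(m, 1L, hr_stat_one)
}

# Data-driven smooth statistic: cumulative Fourier energies N_k with a
# Schwarz-type penalty (each harmonic adds a cosine and a sine score, hence
# 2*k*log(n)); dimension = first k attaining the penalised maximum.
bogdan_stat_m <- function(m, max_dim = 10L) {
  n <- ncol(m)
  reps <- nrow(m)
  Nk <- matrix(0, reps, max_dim)
  acc <- numeric(reps)
  for (j in seq_len(max_dim)) {
    cj <- rowSums(cos(j * m)) * sqrt(2 / n)
    sj <- rowSums(sin(j * m)) * sqrt(2 / n)
    acc <- acc + cj^2 + sj^2
    Nk[, j] <- acc
  }
  crit <- sweep(Nk, 2L, 2 * seq_len(max_dim) * log(n), "-")
  k <- max.col(crit, ties.method = "first")
  list(stat = Nk[cbind(seq_len(reps), k)], dim = k)
}

# ---- analytic p-values ----------------------------------------------------

p_rayleigh_analytic <- function(r, n) {
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  pmin(pmax(p, 0), 1)
}

p_v_analytic <- function(v, n) {
  stats::pnorm(v * sqrt(2 * n), lower.tail = FALSE)
}

p_kuiper_analytic <- function(V, n) {
  K <- V * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  mm <- seq_len(60)
  p <- vapply(K, function(k) {
    if (k < 0.3) return(1)
    sum(2 * (4 * mm^2 * k^2 - 1) * exp(-2 * mm^2 * k^2))
  }, numeric(1))
  pmin(pmax(p, 0), 1)
}

p_watson_analytic <- function(U2, n) {
  # Stephens' finite-n modification, then the asymptotic alternating series
  U2m <- (U2 - 0.1 / n + 0.1 / n^2) * (1 + 0.8 / n)
  mm <- seq_len(100)
  p <- vapply(U2m, function(u) {
    if (u <= 1e-8) return(1)
    2 * sum((-1)^(mm - 1) * exp(-2 * mm^2 * pi^2 * u))
  }, numeric(1))
  pmin(pmax(p, 0), 1)
}

analytic_supported <- c("rayleigh", "v", "kuiper", "watson")

p_analytic <- function(test, stat, n) {
  switch(test,
    rayleigh = p_rayleigh_analytic(stat, n),
    v = p_v_analytic(stat, n),
    kuiper = p_kuiper_analytic(stat, n),
    watson = p_watson_analytic(stat, n),
    stop("no analytic p-value for test '", test, "'", call. = FALSE)
  )
}

# ---- Monte-Carlo null calibration -----------------------------------------

#' Monte-Carlo null calibration for a uniformity test
#'
#' Draws `reps` uniform samples of size `n`, evaluates the test statistic on
#' each, and stores the sorted null statistics. Because the null distribution
#' of every statistic here depends only on `n`, one calibration is reused
#' across all samples of that size -- this is what makes 10,000-replicate
#' power sweeps cheap. Empirical p-values use the
#' `(1 + #\{null >= observed\}) / (reps + 1)` convention, which can never
#' return zero and yields an exactly valid test.
#'
#' @param test one of `"rayleigh"`, `"v"`, `"kuiper"`, `"watson"`, `"rao"`,
#'   `"hermans_rasson"`, `"bogdan"`.
#' @param n sample size the calibration is for.
#' @param reps number of null draws (>= 999); default 9999.
#' @param seed integer seed; the calibration is deterministic given the seed.
#' @param max_dim maximum smooth-test dimension (Bogdan only).
#' @return An object of class `"circ_null"` holding the sorted null
#'   statistics and its provenance (`test`, `n`, `reps`, `seed`).
#' @examples
#' cal <- calibrate_null("hermans_rasson", n = 25, reps = 999, seed = 7)
#' x <- rcirc(25, dist_mixture(c(.5, .5), c(0, pi), c(3, 3)), seed = 1)
#' hermans_rasson_test(x, calibration = cal)
#' @export
calibrate_null <- function(test, n, reps = 9999, seed = 1, max_dim = 10L) {
  test <- match.arg(test, all_tests())
  if (reps < 999) stop("'reps' must be at least 999", call. = FALSE)
  n <- as.integer(n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  m <- matrix(stats::runif(reps * n, 0, 2 * pi), nrow = reps, ncol = n)
  stats_null <- stat_batch(test, m, mu0 = 0, max_dim = max_dim)
  structure(list(test = test, n = n, reps = as.integer(reps), seed = seed,
                 max_dim = max_dim, sorted = sort(stats_null)),
            class = "circ_null")
}

#' @export
print.circ_null <- function(x, ...) {
  cat(sprintf("Monte-Carlo null calibration: %s test, n = %d, %d draws (seed %s)\n",
              x$test, x$n, x$reps, format(x$seed)))
  invisible(x)
}

p_from_null <- function(calib, stat) {
  ge <- calib$reps - findInterval(stat, calib$sorted, left.open = TRUE)
  (1 + ge) / (calib$reps + 1)
}

all_tests <- function() {
  c("rayleigh", "v", "kuiper", "watson", "rao", "hermans_rasson", "bogdan")
}
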