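# Monte-Carlo estimation of type-I error and power. All tests in a scenario
# are evaluated on the SAME simulated samples (paired comparison), and
# Monte-Carlo null tables are computed once per (test, n) and reused across
# the replication loop.

#' Describe one test configuration for the power engine
#'
#' @param test test identifier (see [all] of `"rayleigh"`, `"v"`, `"kuiper"`,
#'   `"watson"`, `"rao"`, `"hermans_rasson"`, `"bogdan"`).
#' @param mu0 pre-specified direction, radians (V-test only).
#' @param ffold optional integer: apply the f-fold transformation to every
#'   sample before testing (e.g. `ffold = 2` gives the "Rayleigh (2x)"
#'   procedure).
#' @param method `"analytic"` or `"monte_carlo"`; defaults to analytic for
#'   Rayleigh/V/Kuiper/Watson and Monte-Carlo for the rest.
#' @param max_dim smooth-test dimension cap (Bogdan only).
#' @param label column label in results; a readable default is built from
#'   the other arguments.
#' @return A list of class `"test_config"`.
#' @examples
#' test_config("rayleigh", ffold = 2)
#' test_config("v", mu0 = deg2rad(20))
#' @export
test_config <- function(test, mu0 = NULL, ffold = NULL, method = NULL,
                        max_dim = 10L, label = NULL) {
  test <- match.arg(test, all_tests())
  if (test == "v" && is.null(mu0)) {
    stop("the V-test configuration needs 'mu0'", call. = FALSE)
  }
  if (is.null(method)) {
    method <- if (test %in% analytic_supported) "analytic" else "monte_carlo"
  }
  method <- match.arg(method, c("analytic", "monte_carlo"))
  if (is.null(label)) {
    label <- test
    if (test == "v") label <- sprintf("v_%g", round(rad2deg(mu0), 6))
    if (!is.null(ffold)) label <- sprintf("%s_%dx", label, as.integer(ffold))
  }
  structure(list(test = test, mu0 = if (is.null(mu0)) 0 else mu0 %% (2 * pi),
                 ffold = if (is.null(ffold)) NULL else as.integer(ffold),
                 method = method, max_dim = as.integer(max_dim),
                 label = label),
            class = "test_config")
}

as_test_config <- function(x) {
  if (inherits(x, "test_config")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x == "v") stop("specify the V-test via test_config('v', mu0 = ...)",
                       call. = FALSE)
    return(test_config(x))
  }
  stop("tests must be test names or test_config() objects", call. = FALSE)
}

# p-values of one configuration on a matrix of samples
pvals_config <- function(cfg, m, null_cache, null_reps, master_seed) {
  if (!is.null(cfg$ffold)) m <- (cfg$ffold * m) %% (2 * pi)
  n <- ncol(m)
  st <- stat_batch(cfg$test, m, mu0 = cfg$mu0, max_dim = cfg$max_dim)
  if (cfg$method == "analytic") {
    p_analytic(cfg$test, st, n)
  } else {
    cal <- get_null_cached(null_cache, cfg$test, n, null_reps, master_seed,
                           cfg$max_dim)
    p_from_null(cal, st)
  }
}

get_null_cached <- function(cache, test, n, reps, master_seed, max_dim) {
  key <- sprintf("%s|%d|%d", test, n, max_dim)
  if (!is.null(cache[[key]])) return(cache[[key]])
  cal <- calibrate_null(test, n, reps = reps,
                        seed = hash_seed(master_seed, paste0("null|", key)),
                        max_dim = max_dim)
  cache[[key]] <- cal
  cal
}

dist_key <- function(spec) {
  pars <- spec[setdiff(names(spec), "family")]
  paste(spec$family,
        paste(vapply(unlist(pars), format, character(1), digits = 15),
              collapse = ","), sep = ":")
}

# deterministic 31-bit sub-seed from a master seed and a string key
hash_seed <- function(master, key) {
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Estimate the rejection rate of one test under one generator
#'
#' Draws `reps` samples of size `n` from `spec`, applies the test, and
#' returns the proportion of p-values below `alpha` together with its
#' binomial Monte-Carlo standard error `sqrt(p*(1-p)/reps)`. Under the
#' uniform generator this estimates the type-I error rate; under any other
#' generator, power.
#'
#' @param test a test name or [test_config()].
#' @param spec a `"circ_dist"` generator.
#' @param n sample size.
#' @param reps number of simulated samples (>= 100).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @param null_reps Monte-Carlo null-table size for tests that need one.
#' @return A list with `power`, `se`, `rejections`, `reps`.
#' @examples
#' estimate_rejection_rate("rayleigh", dist_vonmises(0, 6), n = 100,
#'                         reps = 200, seed = 1)
#' @export
estimate_rejection_rate <- function(test, spec, n, reps, alpha = 0.05,
                                    seed = 1, null_reps = 9999) {
  cfg <- as_test_config(test)
  stopifnot(inherits(spec, "circ_dist"))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  # a degenerate one-cell scenario, so a grid cell and a direct estimate are
  # the same computation by construction
  sc <- structure(list(name = "single", alpha = alpha, kappa = NA_real_,
                       sweep_name = "none", sweep_values = 0,
                       sample_sizes = n, reps = reps,
                       tests = list(cfg),
                       make_dist = function(v, kappa) spec),
                  class = "circ_scenario")
  row <- run_scenario(sc, seed = seed, null_reps = null_reps)
  list(power = row$power, se = row$se, rejections = row$rejections,
       reps = row$reps)
}

#' Simulation scenarios for the power study
#'
#' `scenario()` builds a `"circ_scenario"`: a generator family with one swept
#' parameter, a set of sample sizes, a set of test configurations, and
#' default replication counts. The presets cover the standard sweeps of the
#' power study; every field can be overridden.
#'
#' Presets:
#' \describe{
#'   \item{`type1`}{uniform generator, n in 10, 15, 20, 25, 30, 40, 80, 100;
#'     all seven tests; 100,000 reps by default.}
#'   \item{`unimodal_vm`}{von Mises, mean 0, kappa swept (default 0 to 4 by
#'     0.5); n in 15, 25, 40, 100; Rayleigh, Kuiper, Watson, Rao, and the
#'     V-test with its direction at 0, 20 and 45 degrees off the true mean.}
#'   \item{`unimodal_wrapped_cauchy`}{wrapped Cauchy, rho swept (0 to 0.8 by
#'     0.1); same tests.}
#'   \item{`unimodal_skew_normal`}{wrapped skew-normal, location 0, shape 30
#'     (right skew), dispersion omega swept (0.5 to 5 by 0.5); power falls as
#'     omega grows. Rayleigh, Kuiper, Watson, Rao.}
#'   \item{`bimodal_sym`}{equal mixture with modes 0 and 180 degrees, shared
#'     kappa swept 0 to 6 by 0.1, n = 25; Rayleigh raw and 2x-transformed,
#'     Kuiper, Watson, Rao, Hermans-Rasson, Bogdan.}
#'   \item{`bimodal_asym`}{modes 0 and 90 degrees, otherwise as above.}
#'   \item{`multimodal`}{`n_modes` (3 to 6) equal modes, `placement`
#'     symmetric or asymmetric, kappa swept; Rayleigh raw and f-fold, plus
#'     the omnibus tests.}
#'   \item{`bimodal_delta`}{two equal modes, angular separation delta swept
#'     0 to 180 degrees (10 degree steps), shared `kappa` (default 3);
#'     n in 15, 25, 40, 100.}
#'   \item{`bimodal_kappa2`}{modes 0/180 (or 0/90 with
#'     `placement = "asymmetric"`), kappa of the first mode fixed at 3,
#'     kappa of the second swept 0 to 6 by 0.1; n = 25.}
#'   \item{`bimodal_weights`}{modes 0/180 (or 0/90), shared `kappa` (default
#'     3, 2 also used), weight of the first mode swept 0.05 to 0.5 by 0.05;
#'     n = 25.}
#' }
#'
#' @param name preset name, see Details.
#' @param sweep_values,sample_sizes,tests,reps,alpha overrides of the preset.
#' @param kappa shared concentration for the delta/weights presets.
#' @param n_modes,placement mode layout for the `multimodal` preset.
#' @return A list of class `"circ_scenario"`.
#' @examples
#' sc <- scenario("bimodal_sym", sweep_values = 3, reps = 500)
#' run_scenario(sc, seed = 1)
#' @export
scenario <- function(name = c("type1", "unimodal_vm", "unimodal_wrapped_cauchy",
                              "unimodal_skew_normal", "bimodal_sym",
                              "bimodal_asym", "multimodal", "bimodal_delta",
                              "bimodal_kappa2", "bimodal_weights"),
                     sweep_values = NULL, sample_sizes = NULL, tests = NULL,
                     reps = NULL, alpha = 0.05, kappa = 3,
                     n_modes = 3, placement = c("symmetric", "asymmetric")) {
  name <- match.arg(name)
  placement <- match.arg(placement)
  v_offsets <- function() list(
    test_config("v", mu0 = 0, label = "v_0"),
    test_config("v", mu0 = deg2rad(20), label = "v_20"),
    test_config("v", mu0 = deg2rad(45), label = "v_45"))
  omnibus <- function() list(test_config("kuiper"), test_config("watson"),
                             test_config("rao"),
                             test_config("hermans_rasson"),
                             test_config("bogdan"))
  preset <- switch(name,
    type1 = list(
      sweep_name = "none", sweep_values = 0,
      sample_sizes = c(10, 15, 20, 25, 30, 40, 80, 100), reps = 100000,
      tests = c(list(test_config("rayleigh"),
                     test_config("v", mu0 = 0, label = "v_0")), omnibus()),
      make_dist = function(v, kappa) dist_uniform()),
    unimodal_vm = list(
      sweep_name = "kappa", sweep_values = seq(0, 4, by = 0.5),
      sample_sizes = c(15, 25, 40, 100), reps = 10000,
      tests = c(list(test_config("rayleigh"), test_config("kuiper"),
                     test_config("watson"), test_config("rao")), v_offsets()),
      make_dist = function(v, kappa) dist_vonmises(mu = 0, kappa = v)),
    unimodal_wrapped_cauchy = list(
      sweep_name = "rho", sweep_values = seq(0, 0.8, by = 0.1),
      sample_sizes = c(15, 25, 40, 100), reps = 10000,
      tests = c(list(test_config("rayleigh"), test_config("kuiper"),
                     test_config("watson"), test_config("rao")), v_offsets()),
      make_dist = function(v, kappa) dist_wrappedcauchy(mu = 0, rho = v)),
    unimodal_skew_normal = list(
      sweep_name = "omega", sweep_values = seq(0.5, 5, by = 0.5),
      sample_sizes = c(15, 25, 40, 100), reps = 10000,
      tests = list(test_config("rayleigh"), test_config("kuiper"),
                   test_config("watson"), test_config("rao")),
      make_dist = function(v, kappa)
        dist_wrappedskewnormal(epsilon = 0, omega = v, alpha = 30)),
    bimodal_sym = list(
      sweep_name = "kappa", sweep_values = seq(0, 6, by = 0.1),
      sample_sizes = 25, reps = 10000,
      tests = c(list(test_config("rayleigh"),
                     test_config("rayleigh", ffold = 2)), omnibus()),
      make_dist = function(v, kappa) mixture_modes(2, "symmetric", kappa = v)),
    bimodal_asym = list(
      sweep_name = "kappa", sweep_values = seq(0, 6, by = 0.1),
      sample_sizes = 25, reps = 10000,
      tests = c(list(test_config("rayleigh"),
                     test_config("rayleigh", ffold = 2)), omnibus()),
      make_dist = function(v, kappa) mixture_modes(2, "asymmetric", kappa = v)),
    multimodal = list(
      sweep_name = "kappa", sweep_values = seq(0, 6, by = 0.1),
      sample_sizes = 25, reps = 10000,
      tests = c(list(test_config("rayleigh"),
                     test_config("rayleigh", ffold = as.integer(n_modes))),
                omnibus()),
      make_dist = local({
        nm <- n_modes; pl <- placement
        function(v, kappa) mixture_modes(nm, pl, kappa = v)
      })),
    bimodal_delta = list(
      sweep_name = "delta_deg", sweep_values = seq(0, 180, by = 10),
      sample_sizes = c(15, 25, 40, 100), reps = 10000,
      tests = c(list(test_config("rayleigh")), omnibus()),
      make_dist = function(v, kappa)
        dist_mixture(c(0.5, 0.5), c(0, deg2rad(v)), c(kappa, kappa))),
    bimodal_kappa2 = list(
      sweep_name = "kappa2", sweep_values = seq(0, 6, by = 0.1),
      sample_sizes = 25, reps = 10000,
      tests = c(list(test_config("rayleigh")), omnibus()),
      make_dist = local({
        pl <- placement
        function(v, kappa) {
          mus <- if (pl == "symmetric") c(0, pi) else c(0, pi / 2)
          dist_mixture(c(0.5, 0.5), mus, c(3, v))
        }
      })),
    bimodal_weights = list(
      sweep_name = "weight", sweep_values = seq(0.05, 0.5, by = 0.05),
      sample_sizes = 25, reps = 10000,
      tests = c(list(test_config("rayleigh")), omnibus()),
      make_dist = local({
        pl <- placement
        function(v, kappa) {
          mus <- if (pl == "symmetric") c(0, pi) else c(0, pi / 2)
          dist_mixture(c(v, 1 - v), mus, c(kappa, kappa))
        }
      }))
  )
  if (!is.null(sweep_values)) {
    if (length(sweep_values) < 1L || is.unsorted(sweep_values, strictly = TRUE))
      stop("'sweep_values' must be non-empty and strictly increasing",
           call. = FALSE)
    preset$sweep_values <- sweep_values
  }
  if (!is.null(sample_sizes)) preset$sample_sizes <- sample_sizes
  if (!is.null(tests)) preset$tests <- lapply(tests, as_test_config)
  if (!is.null(reps)) preset$reps <- reps
  if (preset$reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  structure(c(list(name = name, alpha = alpha, kappa = kappa), preset),
            class = "circ_scenario")
}

#' @export
print.circ_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': sweep %s over %d values, n in {%s}, %d tests, %d reps, alpha = %g\n",
              x$name, x$sweep_name, length(x$sweep_values),
              paste(x$sample_sizes, collapse = ", "), length(x$tests),
              x$reps, x$alpha))
  invisible(x)
}

#' Run a simulation scenario
#'
#' Evaluates the full (sweep value x sample size x test) grid of a
#' [scenario()]. For each cell, `reps` samples are drawn from the generator
#' (per-cell RNG streams derived deterministically from `seed` and the grid
#' coordinates, so any cell can be re-run in isolation) and every test
#' configuration is applied to the same samples, which removes
#' between-test Monte-Carlo noise from power comparisons. Null tables for
#' Monte-Carlo-calibrated tests are computed once per (test, n).
#'
#' @param spec a `"circ_scenario"`.
#' @param seed master integer seed.
#' @param reps optional override of the scenario's replication count.
#' @param null_reps Monte-Carlo null-table size; default 9999.
#' @return A data frame of class `"power_result"` with columns `scenario`,
#'   `test`, `n`, `sweep_name`, `sweep_value`, `rejections`, `reps`, `power`,
#'   `se`.
#' @examples
#' res <- run_scenario(scenario("bimodal_sym", sweep_values = 3, reps = 500),
#'                     seed = 1, null_reps = 999)
#' res[order(-res$power), c("test", "power", "se")]
#' @export
run_scenario <- function(spec, seed = 1, reps = NULL, null_reps = 9999) {
  stopifnot(inherits(spec, "circ_scenario"))
  if (is.null(reps)) reps <- spec$reps
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(spec$sample_sizes) * length(spec$sweep_values))
  ri <- 0L
  for (n in spec$sample_sizes) {
    n <- as.integer(n)
    # pre-build null tables (own derived seeds, independent of cell order)
    for (cfg in spec$tests) {
      if (cfg$method == "monte_carlo") {
        get_null_cached(cache, cfg$test, n, null_reps, seed, cfg$max_dim)
      }
    }
    for (si in seq_along(spec$sweep_values)) {
      v <- spec$sweep_values[si]
      gen <- spec$make_dist(v, spec$kappa)
      # key the cell stream by (n, generator), not grid position, so a cell
      # gives the same draws whether run alone, inside the full grid, or
      # through estimate_rejection_rate
      set.seed(hash_seed(seed, sprintf("cell|%d|%s", n, dist_key(gen))))
      m <- matrix(rcirc_raw(reps * n, gen), nrow = reps, ncol = n)
      cell <- lapply(spec$tests, function(cfg) {
        p <- pvals_config(cfg, m, cache, null_reps, seed)
        rej <- sum(p < spec$alpha)
        ph <- rej / reps
        data.frame(scenario = spec$name, test = cfg$label, n = n,
                   sweep_name = spec$sweep_name, sweep_value = v,
                   rejections = rej, reps = as.integer(reps), power = ph,
                   se = sqrt(ph * (1 - ph) / reps),
                   stringsAsFactors = FALSE)
      })
      ri <- ri + 1L
      rows[[ri]] <- do.call(rbind, cell)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_result", "data.frame")
  out
}

#' @export
print.power_result <- function(x, ...) {
  lab <- if (is.null(x$scenario)) "" else
    sprintf(" (%s)", paste(unique(x$scenario), collapse = ", "))
  cat(sprintf("Power/type-I estimates: %d cells%s\n", nrow(x), lab))
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' Basic power-curve plot
#'
#' Plots estimated power against the swept parameter, one line per test, one
#' panel per sample size.
#'
#' @param x a `"power_result"` from [run_scenario()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.power_result <- function(x, ...) {
  ns <- sort(unique(x$n))
  tests <- unique(x$test)
  oldpar <- graphics::par(mfrow = c(1, length(ns)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar), add = TRUE)
  for (n in ns) {
    sub <- x[x$n == n, ]
    sv <- sort(unique(sub$sweep_value))
    mat <- sapply(tests, function(tt)
      sub$power[match(paste(sv, tt), paste(sub$sweep_value, sub$test))])
    graphics::matplot(sv, mat, type = "l", lty = 1, lwd = 2,
                      col = seq_along(tests), ylim = c(0, 1),
                      xlab = sub$sweep_name[1], ylab = "power",
                      main = sprintf("n = %d", n), ...)
    graphics::abline(h = 0.05, lty = 3, col = "grey40")
    graphics::legend("bottomright", legend = tests, col = seq_along(tests),
                     lty = 1, lwd = 2, cex = 0.7, bty = "n")
  }
  invisible(x)
}
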