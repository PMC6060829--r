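# Public single-sample uniformity tests. Each returns an htest-compatible
# object so print() gives the familiar layout; extra fields (test_name,
# mc_reps, mu0, f_used) carry the calibration metadata.

circ_test_result <- function(test_name, stat_name, statistic, p, n, method,
                             data_name, mc_reps = NULL, mu0 = NULL,
                             f_used = NULL, extra = list(), method_label) {
  stat <- statistic
  names(stat) <- stat_name
  out <- c(list(
    statistic = stat,
    parameter = c(n = n),
    p.value = unname(p),
    method = method_label,
    data.name = data_name,
    test_name = test_name,
    calibration_method = method,
    mc_reps = mc_reps,
    mu0 = mu0,
    f_used = f_used
  ), extra)
  structure(out, class = c("circ_test", "htest"))
}

mc_p_single <- function(test, x, calibration, mc_reps, seed, max_dim = 10L) {
  if (is.null(calibration)) {
    calibration <- calibrate_null(test, length(x), reps = mc_reps,
                                  seed = if (is.null(seed)) 1L else seed,
                                  max_dim = max_dim)
  } else {
    if (!inherits(calibration, "circ_null")) {
      stop("'calibration' must come from calibrate_null()", call. = FALSE)
    }
    if (calibration$test != test) {
      stop(sprintf("calibration is for the '%s' test, not '%s'",
                   calibration$test, test), call. = FALSE)
    }
    if (calibration$n != length(x)) {
      stop(sprintf("calibration n = %d does not match sample n = %d",
                   calibration$n, length(x)), call. = FALSE)
    }
  }
  calibration
}

#' Rayleigh test of circular uniformity
#'
#' The classical test against a unimodal (von Mises) alternative: the
#' statistic is the mean resultant length r, large values rejecting
#' uniformity. The analytic p-value uses the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n*r`;
#' a Monte-Carlo route through [calibrate_null()] is also available and is
#' the default for very small samples (n < 4) where the approximation is
#' poor. The Rayleigh test has low power against multimodal departures; for
#' data with f modes mirrored around the circle, supply `f` to apply the
#' f-fold transformation first (the "Rayleigh (f-fold)" procedure), with f
#' fixed before looking at the data.
#'
#' @param x an [angles] object or numeric vector of radians.
#' @param method `"analytic"` or `"monte_carlo"`; default analytic for
#'   n >= 4, Monte-Carlo otherwise.
#' @param f optional integer fold for a pre-applied f-fold transformation;
#'   recorded in the result.
#' @param mc_reps Monte-Carlo null draws when no calibration is given.
#' @param seed seed for the Monte-Carlo null.
#' @param calibration an optional precomputed [calibrate_null()] object.
#' @return A `"circ_test"` (htest-compatible) object.
#' @examples
#' x <- rcirc(25, dist_vonmises(mu = 0, kappa = 2), seed = 1)
#' rayleigh_test(x)
#' @export
rayleigh_test <- function(x, method = NULL, f = NULL, mc_reps = 9999,
                          seed = NULL, calibration = NULL) {
  dn <- deparse1(substitute(x))
  x <- as_angles(x)
  f_used <- NULL
  if (!is.null(f)) {
    x <- ffold_transform(x, f)
    f_used <- as.integer(f)
  }
  n <- length(x)
  if (is.null(method)) method <- if (n >= 4) "analytic" else "monte_carlo"
  method <- match.arg(method, c("analytic", "monte_carlo"))
  v <- as.numeric(x)
  r <- stat_batch("rayleigh", matrix(v, nrow = 1L))
  if (method == "analytic") {
    p <- p_rayleigh_analytic(r, n)
    reps <- NULL
  } else {
    cal <- mc_p_single("rayleigh", v, calibration, mc_reps, seed)
    p <- p_from_null(cal, r)
    reps <- cal$reps
  }
  lbl <- if (is.null(f_used)) "Rayleigh test of circular uniformity" else
    sprintf("Rayleigh test of circular uniformity (%d-fold transformed)", f_used)
  circ_test_result("rayleigh", "r", r, p, n, method, dn, mc_reps = reps,
                   f_used = f_used, method_label = lbl)
}

#' V-test (modified Rayleigh test) with a pre-specified direction
#'
#' One-sided Rayleigh variant for the case where the researcher can name the
#' expected direction `mu0` before seeing the data. The statistic is
#' `V = r * cos(thetabar - mu0)`; significance comes from `u = V * sqrt(2n)`
#' against the standard normal upper tail (or Monte-Carlo). The alternative
#' hypothesis is the same as the Rayleigh test's, so a significant V-test by
#' itself does not demonstrate concentration around `mu0`: always read it
#' together with [mean_direction_ci()]. `mu0` must be fixed before any
#' inspection of the data or the type-I error rate is inflated.
#'
#' @inheritParams rayleigh_test
#' @param mu0 pre-specified mean direction.
#' @param mu0_unit unit of `mu0`: `"radians"` (default) or `"degrees"`.
#' @return A `"circ_test"` object; `$mu0` records the direction (radians).
#' @examples
#' x <- rcirc(25, dist_vonmises(mu = 0, kappa = 1.5), seed = 1)
#' v_test(x, mu0 = 0)
#' @export
v_test <- function(x, mu0, mu0_unit = c("radians", "degrees"), method = NULL,
                   mc_reps = 9999, seed = NULL, calibration = NULL) {
  dn <- deparse1(substitute(x))
  if (missing(mu0)) {
    stop("the V-test requires a pre-specified mean direction 'mu0'",
         call. = FALSE)
  }
  mu0_unit <- match.arg(mu0_unit)
  if (mu0_unit == "degrees") mu0 <- deg2rad(mu0)
  mu0 <- mu0 %% (2 * pi)
  x <- as_angles(x)
  n <- length(x)
  if (is.null(method)) method <- if (n >= 4) "analytic" else "monte_carlo"
  method <- match.arg(method, c("analytic", "monte_carlo"))
  v <- as.numeric(x)
  V <- stat_batch("v", matrix(v, nrow = 1L), mu0 = mu0)
  if (method == "analytic") {
    p <- p_v_analytic(V, n)
    reps <- NULL
  } else {
    cal <- mc_p_single("v", v, calibration, mc_reps, seed)
    p <- p_from_null(cal, V)
    reps <- cal$reps
  }
  circ_test_result("v", "V", V, p, n, method, dn, mc_reps = reps, mu0 = mu0,
                   extra = list(u = V * sqrt(2 * n)),
                   method_label = "V-test of circular uniformity (specified direction)")
}

#' Kuiper's test of circular uniformity
#'
#' Rotation-invariant analogue of the Kolmogorov-Smirnov test:
#' `V_n = D+ + D-` on the sorted angles scaled to `[0, 1)`. The analytic
#' p-value applies the standard asymptotic series to
#' `V_n * (sqrt(n) + 0.155 + 0.24/sqrt(n))`.
#'
#' @inheritParams rayleigh_test
#' @return A `"circ_test"` object.
#' @export
kuiper_test <- function(x, method = c("analytic", "monte_carlo"),
                        mc_reps = 9999, seed = NULL, calibration = NULL) {
  dn <- deparse1(substitute(x))
  method <- match.arg(method)
  x <- as_angles(x)
  n <- length(x)
  if (n < 2) stop("Kuiper's test needs at least 2 angles", call. = FALSE)
  v <- as.numeric(x)
  Vn <- stat_batch("kuiper", matrix(v, nrow = 1L))
  if (method == "analytic") {
    p <- p_kuiper_analytic(Vn, n)
    reps <- NULL
  } else {
    cal <- mc_p_single("kuiper", v, calibration, mc_reps, seed)
    p <- p_from_null(cal, Vn)
    reps <- cal$reps
  }
  circ_test_result("kuiper", "Vn", Vn, p, n, method, dn, mc_reps = reps,
                   method_label = "Kuiper's test of circular uniformity")
}

#' Watson's U-squared test of circular uniformity
#'
#' Rotation-invariant Cramer-von Mises analogue:
#' `U2 = sum_i (u_i - ubar - (2i-1)/(2n) + 1/2)^2 + 1/(12n)`. The analytic
#' p-value uses the asymptotic alternating series after Stephens'
#' finite-sample modification.
#'
#' @inheritParams rayleigh_test
#' @return A `"circ_test"` object.
#' @export
watson_test <- function(x, method = c("analytic", "monte_carlo"),
                        mc_reps = 9999, seed = NULL, calibration = NULL) {
  dn <- deparse1(substitute(x))
  method <- match.arg(method)
  x <- as_angles(x)
  n <- length(x)
  if (n < 2) stop("Watson's test needs at least 2 angles", call. = FALSE)
  v <- as.numeric(x)
  U2 <- stat_batch("watson", matrix(v, nrow = 1L))
  if (method == "analytic") {
    p <- p_watson_analytic(U2, n)
    reps <- NULL
  } else {
    cal <- mc_p_single("watson", v, calibration, mc_reps, seed)
    p <- p_from_null(cal, U2)
    reps <- cal$reps
  }
  circ_test_result("watson", "U2", U2, p, n, method, dn, mc_reps = reps,
                   method_label = "Watson's U2 test of circular uniformity")
}

#' Rao's spacing test of circular uniformity
#'
#' Based on the arc lengths between successive order statistics (including
#' the wrap-around arc): `U = 1/2 * sum |T_i - 2*pi/n|`. Under uniformity
#' all spacings are near `2*pi/n`, so large U rejects. Published critical
#' tables are coarse, so p-values are Monte-Carlo by default. Ties
#' (duplicate angles, zero spacings) are legal.
#'
#' @inheritParams rayleigh_test
#' @return A `"circ_test"` object.
#' @export
rao_spacing_test <- function(x, mc_reps = 9999, seed = NULL,
                             calibration = NULL) {
  dn <- deparse1(substitute(x))
  x <- as_angles(x)
  n <- length(x)
  if (n < 4) stop("Rao's spacing test needs at least 4 angles", call. = FALSE)
  v <- as.numeric(x)
  U <- stat_batch("rao", matrix(v, nrow = 1L))
  cal <- mc_p_single("rao", v, calibration, mc_reps, seed)
  circ_test_result("rao", "U", U, p_from_null(cal, U), n, "monte_carlo", dn,
                   mc_reps = cal$reps,
                   method_label = "Rao's spacing test of circular uniformity")
}

#' Hermans-Rasson test of circular uniformity
#'
#' An omnibus test built for multimodal alternatives. The statistic is a
#' rotation-invariant sum over all pairwise angle differences,
#' `T = (1/n) * sum_ij [ (pi/2 - d(theta_i, theta_j))
#'   + 2.895 * (2/pi - |sin(theta_i - theta_j)|) ]`,
#' where `d` is circular distance: the distance term carries the odd Fourier
#' harmonics (unimodal departures), the `|sin|` term the even harmonics
#' (bimodal and mirrored departures), so the test keeps its power where the
#' Rayleigh test collapses. There is no closed-form null, so p-values come
#' from the shared Monte-Carlo calibration.
#'
#' @inheritParams rayleigh_test
#' @return A `"circ_test"` object.
#' @examples
#' x <- rcirc(25, mixture_modes(2, "symmetric", kappa = 3), seed = 1)
#' hermans_rasson_test(x, mc_reps = 999, seed = 2)
#' @export
hermans_rasson_test <- function(x, mc_reps = 9999, seed = NULL,
                                calibration = NULL) {
  dn <- deparse1(substitute(x))
  x <- as_angles(x)
  n <- length(x)
  if (n < 4) stop("the Hermans-Rasson test needs at least 4 angles",
                  call. = FALSE)
  v <- as.numeric(x)
  Tstat <- stat_batch("hermans_rasson", matrix(v, nrow = 1L))
  cal <- mc_p_single("hermans_rasson", v, calibration, mc_reps, seed)
  circ_test_result("hermans_rasson", "T", Tstat, p_from_null(cal, Tstat), n,
                   "monte_carlo", dn, mc_reps = cal$reps,
                   method_label = "Hermans-Rasson test of circular uniformity")
}

#' Data-driven smooth test of circular uniformity (after Bogdan)
#'
#' A smooth test whose dimension is chosen from the data: Fourier scores
#' `c_j = sqrt(2/n) * sum cos(j*theta_i)`, `s_j = sqrt(2/n) * sum
#' sin(j*theta_i)` accumulate into `N_k = sum_{j<=k} (c_j^2 + s_j^2)`, the
#' dimension `k*` maximises the Schwarz-penalised `N_k - 2*k*log(n)` (each
#' harmonic counts its cosine and sine score as two parameters, ties to the
#' smallest k), and the statistic is `N_{k*}`. Because the selection step is
#' part of the statistic, it is re-run inside every Monte-Carlo null draw --
#' calibrating against a fixed-dimension null would make the test
#' anti-conservative.
#'
#' @inheritParams rayleigh_test
#' @param max_dim largest dimension considered (>= 1); default 10.
#' @return A `"circ_test"` object; `$selected_dim` holds k*.
#' @export
bogdan_test <- function(x, max_dim = 10L, mc_reps = 9999, seed = NULL,
                        calibration = NULL) {
  dn <- deparse1(substitute(x))
  if (max_dim < 1) stop("'max_dim' must be >= 1", call. = FALSE)
  x <- as_angles(x)
  n <- length(x)
  if (n < 5) stop("the smooth test needs at least 5 angles", call. = FALSE)
  v <- as.numeric(x)
  bs <- bogdan_stat_m(matrix(v, nrow = 1L), max_dim = max_dim)
  cal <- mc_p_single("bogdan", v, calibration, mc_reps, seed,
                     max_dim = max_dim)
  if (cal$max_dim != max_dim) {
    stop("calibration max_dim does not match", call. = FALSE)
  }
  circ_test_result("bogdan", "N", bs$stat, p_from_null(cal, bs$stat), n,
                   "monte_carlo", dn, mc_reps = cal$reps,
                   extra = list(selected_dim = bs$dim),
                   method_label = "Data-driven smooth test of circular uniformity")
}
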