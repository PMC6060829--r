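#' Directional summary of a circular sample
#'
#' Computes the two descriptive statistics every uniformity test builds on:
#' the mean direction theta-bar = atan2(sum sin, sum cos) and the mean
#' resultant length r = |sum exp(i*theta)| / n. r measures concentration:
#' r = 0 for perfectly balanced samples, r = 1 only when all angles coincide.
#'
#' When r is numerically zero (below `tol`) the mean direction of the sample
#' is undefined -- any direction is as good as any other -- and the summary
#' flags it as such.
#'
#' @param x an [angles] object or numeric vector of radians.
#' @param tol r below this is treated as zero and the mean direction flagged
#'   undefined. Default `1e-12`, which catches exactly symmetric grids.
#' @return A list of class `"circ_summary"` with elements `n`,
#'   `mean_direction` (radians in `[0, 2*pi)`, `NA` when undefined),
#'   `mean_resultant_length`, and `mean_defined`.
#' @examples
#' circ_summary(angles(c(0, pi / 2)))          # r = sqrt(2)/2, mean = pi/4
#' circ_summary(angles(c(0, pi/2, pi, 3*pi/2)))  # r = 0, mean undefined
#' @export
circ_summary <- function(x, tol = 1e-12) {
  x <- as_angles(x)
  n <- length(x)
  C <- sum(cos(x))
  S <- sum(sin(x))
  r <- sqrt(C^2 + S^2) / n
  defined <- r > tol
  mu <- if (defined) atan2(S, C) %% (2 * pi) else NA_real_
  structure(
    list(n = n, mean_direction = mu, mean_resultant_length = min(r, 1),
         mean_defined = defined, unit_hint = unit_hint(x)),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat("Directional summary\n")
  cat(sprintf("  n                     = %d\n", x$n))
  if (x$mean_defined) {
    if (x$unit_hint == "degrees") {
      cat(sprintf("  mean direction        = %.4f deg\n",
                  rad2deg(x$mean_direction)))
    } else {
      cat(sprintf("  mean direction        = %.6f rad\n", x$mean_direction))
    }
  } else {
    cat("  mean direction        = undefined (r ~ 0)\n")
  }
  cat(sprintf("  mean resultant length = %.6f\n", x$mean_resultant_length))
  invisible(x)
}

#' f-fold symmetry transformation
#'
#' Maps each angle theta to `(f * theta) mod 2*pi`. A distribution with exact
#' f-fold symmetry (f equal modes evenly spaced around the circle) becomes
#' unimodal under this map, after which the Rayleigh test regains its power.
#' The fold number f must be chosen before inspecting the data, otherwise the
#' type-I error rate is inflated.
#'
#' @param x an [angles] object or numeric vector of radians.
#' @param f positive integer fold number; `f = 1` is the identity.
#' @return An [angles] object of the same length and unit hint.
#' @examples
#' ffold_transform(angles(c(0, 180), unit = "degrees"), f = 2)  # collapses
#' @export
ffold_transform <- function(x, f) {
  x <- as_angles(x)
  if (length(f) != 1L || !is.finite(f) || f < 1 || f != round(f)) {
    stop("'f' must be a single integer >= 1", call. = FALSE)
  }
  structure((f * as.numeric(x)) %% (2 * pi),
            unit_hint = unit_hint(x), class = "angles")
}

#' Bootstrap confidence interval for the mean direction
#'
#' Percentile bootstrap on the circle: mean directions of resampled data sets
#' are centred on the observed mean direction (deviations mapped to
#' `(-pi, pi]`), the percentile interval of the deviations is taken, and the
#' arc is shifted back. No distributional assumption is made. A significant
#' V-test should always be read together with this interval: only if the
#' interval is narrow and contains the pre-specified direction does the sample
#' support concentration around that direction.
#'
#' @param x an [angles] object or numeric vector of radians; must have r > 0.
#' @param level confidence level in (0, 1); default 0.95.
#' @param reps bootstrap resamples (>= 200); default 9999.
#' @param seed optional integer seed for reproducibility.
#' @return A list of class `"circ_ci"` with `lower`, `upper` (an arc, in the
#'   sample's input unit, traversed counter-clockwise from lower to upper),
#'   `mean_direction`, `level`, `reps`, and `unit`.
#' @examples
#' x <- rcirc(50, dist_vonmises(mu = pi, kappa = 4), seed = 1)
#' mean_direction_ci(x, reps = 999, seed = 2)
#' @export
mean_direction_ci <- function(x, level = 0.95, reps = 9999, seed = NULL) {
  x <- as_angles(x)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  if (reps < 200) stop("'reps' must be at least 200", call. = FALSE)
  s <- circ_summary(x)
  if (!s$mean_defined) {
    stop("mean direction is undefined (mean resultant length ~ 0); no CI",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n <- s$n
  v <- as.numeric(x)
  idx <- sample.int(n, n * reps, replace = TRUE)
  m <- matrix(v[idx], nrow = reps, ncol = n)
  bm <- atan2(rowMeans(sin(m)), rowMeans(cos(m)))
  dev <- (bm - s$mean_direction + pi) %% (2 * pi) - pi
  qs <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 8)
  lo <- (s$mean_direction + qs[1]) %% (2 * pi)
  hi <- (s$mean_direction + qs[2]) %% (2 * pi)
  unit <- unit_hint(x)
  if (unit == "degrees") {
    out <- list(lower = rad2deg(lo), upper = rad2deg(hi),
                mean_direction = rad2deg(s$mean_direction))
  } else {
    out <- list(lower = lo, upper = hi, mean_direction = s$mean_direction)
  }
  structure(c(out, list(level = level, reps = reps, unit = unit)),
            class = "circ_ci")
}

#' @export
print.circ_ci <- function(x, ...) {
  u <- if (x$unit == "degrees") "deg" else "rad"
  cat(sprintf("%.0f%% bootstrap CI for the mean direction (%d resamples)\n",
              100 * x$level, x$reps))
  cat(sprintf("  mean direction: %.4f %s\n", x$mean_direction, u))
  cat(sprintf("  arc: [%.4f, %.4f] %s (counter-clockwise)\n",
              x$lower, x$upper, u))
  invisible(x)
}

#' Does a circular arc contain a direction?
#'
#' Containment on the circle for the arc returned by [mean_direction_ci()]:
#' the arc runs counter-clockwise from `lower` to `upper`.
#'
#' @param ci a `"circ_ci"` object.
#' @param theta direction to check, in the CI's unit.
#' @return logical.
#' @export
ci_contains <- function(ci, theta) {
  full <- if (ci$unit == "degrees") 360 else 2 * pi
  width <- (ci$upper - ci$lower) %% full
  ((theta - ci$lower) %% full) <= width
}

# save/restore .Random.seed so seeded helpers do not clobber the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
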