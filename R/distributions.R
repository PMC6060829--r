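#' Circular distribution specifications
#'
#' Declarative descriptions of the circular laws the simulation engine draws
#' from: the uniform law, the von Mises law (mean `mu`, concentration
#' `kappa`; `kappa = 0` is uniform), the wrapped Cauchy law (mean `mu`,
#' concentration `rho` in `[0, 1)`; `rho = 0` is uniform), the wrapped
#' skew-normal law (a linear skew-normal with location `epsilon`, dispersion
#' `omega > 0` and shape `alpha` wrapped onto the circle; `alpha != 0` gives
#' an asymmetric distribution), and finite mixtures of von Mises components.
#'
#' All angular parameters are radians. Specs are plain lists of class
#' `"circ_dist"`; pass them to [rcirc()] and [dcirc()].
#'
#' @param mu,epsilon location, radians.
#' @param kappa von Mises concentration, `>= 0`.
#' @param rho wrapped Cauchy concentration, in `[0, 1)`.
#' @param omega skew-normal dispersion, `> 0`.
#' @param alpha skew-normal shape; positive values skew right.
#' @param weights,mus,kappas mixture component weights (positive, normalised
#'   to sum to one on construction), mean directions and concentrations;
#'   equal lengths, at least one component.
#' @return A list of class `"circ_dist"` with a `family` element and the
#'   family's parameters.
#' @examples
#' dist_vonmises(mu = 0, kappa = 3)
#' dist_mixture(weights = c(0.5, 0.5), mus = c(0, pi), kappas = c(3, 3))
#' @name circ_dist
NULL

new_circ_dist <- function(family, ...) {
  structure(list(family = family, ...), class = "circ_dist")
}

#' @rdname circ_dist
#' @export
dist_uniform <- function() new_circ_dist("uniform")

#' @rdname circ_dist
#' @export
dist_vonmises <- function(mu = 0, kappa = 1) {
  stopifnot(is.finite(mu), is.finite(kappa))
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  new_circ_dist("von_mises", mu = mu %% (2 * pi), kappa = kappa)
}

#' @rdname circ_dist
#' @export
dist_wrappedcauchy <- function(mu = 0, rho = 0.5) {
  stopifnot(is.finite(mu), is.finite(rho))
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)", call. = FALSE)
  new_circ_dist("wrapped_cauchy", mu = mu %% (2 * pi), rho = rho)
}

#' @rdname circ_dist
#' @export
dist_wrappedskewnormal <- function(epsilon = 0, omega = 1, alpha = 0) {
  stopifnot(is.finite(epsilon), is.finite(omega), is.finite(alpha))
  if (omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  new_circ_dist("wrapped_skew_normal", epsilon = epsilon %% (2 * pi),
                omega = omega, alpha = alpha)
}

#' @rdname circ_dist
#' @export
dist_mixture <- function(weights, mus, kappas) {
  if (length(weights) < 1L ||
      length(weights) != length(mus) || length(mus) != length(kappas)) {
    stop("'weights', 'mus' and 'kappas' must have equal length >= 1",
         call. = FALSE)
  }
  if (any(weights <= 0)) stop("mixture weights must be positive", call. = FALSE)
  if (any(kappas < 0)) stop("mixture 'kappas' must be >= 0", call. = FALSE)
  w <- weights / sum(weights)
  stopifnot(abs(sum(w) - 1) < 1e-12)
  new_circ_dist("mixture", weights = w, mus = mus %% (2 * pi), kappas = kappas)
}

#' @export
print.circ_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  if (x$family == "mixture") {
    cat(sprintf("Circular distribution: von Mises mixture (%d components)\n",
                length(x$weights)))
    print(data.frame(weight = x$weights, mu_deg = rad2deg(x$mus),
                     kappa = x$kappas))
  } else {
    cat(sprintf("Circular distribution: %s\n", x$family))
    if (length(pars)) {
      cat(paste(sprintf("  %s = %g", names(pars), unlist(pars)),
                collapse = "\n"), "\n")
    }
  }
  invisible(x)
}

#' Equal-weight von Mises mixture on a standard mode layout
#'
#' Builds the mixture layouts used throughout the multimodal power study:
#' `n_modes` equally weighted von Mises components with shared concentration
#' `kappa`, placed either symmetrically (modes at `360/f * k` degrees,
#' k = 0..f-1, i.e. exact f-fold symmetry) or asymmetrically: two modes sit
#' 90 degrees apart, and for f >= 3 the modes are evenly spaced over half
#' the circle at `180/(f-1)` degree increments starting from 0 (f = 4 gives
#' 0, 60, 120, 180 degrees).
#'
#' @param n_modes number of modes, between 2 and 6.
#' @param placement `"symmetric"` or `"asymmetric"`.
#' @param kappa shared concentration, `>= 0`.
#' @return A mixture `"circ_dist"` spec.
#' @examples
#' mixture_modes(4, "symmetric", kappa = 3)   # 0, 90, 180, 270 degrees
#' mixture_modes(4, "asymmetric", kappa = 3)  # 0, 60, 120, 180 degrees
#' @export
mixture_modes <- function(n_modes, placement = c("symmetric", "asymmetric"),
                          kappa = 3) {
  placement <- match.arg(placement)
  if (length(n_modes) != 1L || n_modes < 2 || n_modes > 6 ||
      n_modes != round(n_modes)) {
    stop("'n_modes' must be an integer between 2 and 6", call. = FALSE)
  }
  f <- as.integer(n_modes)
  mus <- if (placement == "symmetric") {
    2 * pi * (0:(f - 1)) / f
  } else if (f == 2L) {
    c(0, pi / 2)            # the bimodal asymmetric layout: modes 90 deg apart
  } else {
    pi / (f - 1) * (0:(f - 1))
  }
  dist_mixture(weights = rep(1 / f, f), mus = mus, kappas = rep(kappa, f))
}

#' Draw a sample from a circular distribution
#'
#' von Mises draws use the Best-Fisher (1979) acceptance-rejection method
#' (exact; `kappa = 0` falls back to uniform). Wrapped Cauchy draws invert a
#' linear Cauchy with scale `-log(rho)` and wrap it. Wrapped skew-normal
#' draws use the standard two-normal representation of the linear
#' skew-normal, wrapped mod 2*pi. Mixtures draw a component index from the
#' weights, then a component draw.
#'
#' @param n number of draws, `>= 1`.
#' @param spec a `"circ_dist"` spec.
#' @param seed optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return An [angles] object of length `n`.
#' @examples
#' x <- rcirc(25, dist_vonmises(mu = 0, kappa = 3), seed = 1)
#' rayleigh_test(x)
#' @export
rcirc <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "circ_dist"))
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  angles(rcirc_raw(n, spec), unit = "radians")
}

# raw draws in radians, no class overhead (used by the batch engine)
rcirc_raw <- function(n, spec) {
  switch(spec$family,
    uniform = stats::runif(n, 0, 2 * pi),
    von_mises = rvm_best_fisher(n, spec$mu, spec$kappa),
    wrapped_cauchy = rwrappedcauchy(n, spec$mu, spec$rho),
    wrapped_skew_normal = rwsn(n, spec$epsilon, spec$omega, spec$alpha),
    mixture = {
      k <- sample.int(length(spec$weights), n, replace = TRUE,
                      prob = spec$weights)
      out <- numeric(n)
      for (j in seq_along(spec$weights)) {
        sel <- which(k == j)
        if (length(sel)) {
          out[sel] <- rvm_best_fisher(length(sel), spec$mus[j], spec$kappas[j])
        }
      }
      out
    },
    stop("unknown family: ", spec$family, call. = FALSE)
  )
}

# Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler
rvm_best_fisher <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc > 0L) {
      u3 <- stats::runif(nacc)
      th <- sign(u3 - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nacc)] <- th
      got <- got + nacc
    }
  }
  (out + mu) %% (2 * pi)
}

rwrappedcauchy <- function(n, mu, rho) {
  if (rho == 0) return(stats::runif(n, 0, 2 * pi))
  scale <- -log(rho)
  x <- mu + scale * tan(pi * (stats::runif(n) - 0.5))
  x %% (2 * pi)
}

# linear skew-normal via the delta-representation, then wrapped
rwsn <- function(n, epsilon, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x <- epsilon + omega * (delta * abs(z1) + sqrt(1 - delta^2) * z2)
  x %% (2 * pi)
}

#' Density of a circular distribution
#'
#' von Mises: `exp(kappa*cos(theta - mu)) / (2*pi*I0(kappa))` (computed with
#' the exponentially scaled Bessel function, stable for large `kappa`).
#' Wrapped Cauchy: `(1 - rho^2) / (2*pi*(1 + rho^2 - 2*rho*cos(theta - mu)))`.
#' Wrapped skew-normal: the wrapped sum `sum_k sn(theta + 2*pi*k)` truncated
#' at `|k| <= ceiling(8 * max(1, omega / (2*pi)))`, wide enough that the
#' neglected tail is far below 1e-12. Mixture: weighted sum of component
#' densities.
#'
#' @param theta angles (any real; reduced mod 2*pi).
#' @param spec a `"circ_dist"` spec.
#' @return Non-negative densities, same length as `theta`; each spec
#'   integrates to 1 over `[0, 2*pi)`.
#' @export
dcirc <- function(theta, spec) {
  stopifnot(inherits(spec, "circ_dist"))
  theta <- as.numeric(theta) %% (2 * pi)
  switch(spec$family,
    uniform = rep(1 / (2 * pi), length(theta)),
    von_mises = dvm(theta, spec$mu, spec$kappa),
    wrapped_cauchy = {
      if (spec$rho == 0) rep(1 / (2 * pi), length(theta))
      else (1 - spec$rho^2) /
        (2 * pi * (1 + spec$rho^2 - 2 * spec$rho * cos(theta - spec$mu)))
    },
    wrapped_skew_normal = dwsn(theta, spec$epsilon, spec$omega, spec$alpha),
    mixture = {
      out <- numeric(length(theta))
      for (j in seq_along(spec$weights)) {
        out <- out + spec$weights[j] * dvm(theta, spec$mus[j], spec$kappas[j])
      }
      out
    },
    stop("unknown family: ", spec$family, call. = FALSE)
  )
}

dvm <- function(theta, mu, kappa) {
  if (kappa < 1e-10) return(rep(1 / (2 * pi), length(theta)))
  # exp(kappa*cos(d))/I0(kappa) with both sides scaled by exp(-kappa)
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

dwsn <- function(theta, epsilon, omega, alpha) {
  K <- ceiling(8 * max(1, omega / (2 * pi)))
  out <- numeric(length(theta))
  for (k in -K:K) {
    x <- theta + 2 * pi * k
    z <- (x - epsilon) / omega
    out <- out + 2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
  }
  out
}
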