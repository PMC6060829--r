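#' Construct an angle sample
#'
#' Angles live on the circle: 0 and 2*pi are the same point, so 355 degrees is
#' closer to 5 degrees than to 330 degrees. `angles()` stores a sample in a
#' single canonical form -- radians reduced to `[0, 2*pi)` -- while remembering
#' which unit the data arrived in, so results can be echoed back in that unit.
#'
#' @param x numeric vector of angles (length >= 1, all finite).
#' @param unit unit of `x`: `"radians"` (default) or `"degrees"`.
#' @return An object of class `"angles"`: a numeric vector in radians on
#'   `[0, 2*pi)` with attribute `unit_hint` recording the input unit.
#' @examples
#' a <- angles(c(355, 5, 330), unit = "degrees")
#' circ_summary(a)
#' @export
angles <- function(x, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  x <- as.numeric(x)
  if (length(x) < 1L) {
    stop("empty angle sample: at least one angle is required", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  if (unit == "degrees") x <- x * pi / 180
  structure(x %% (2 * pi), unit_hint = unit, class = "angles")
}

#' @rdname angles
#' @export
as_angles <- function(x, unit = "radians") {
  if (inherits(x, "angles")) return(x)
  angles(x, unit = unit)
}

#' @export
print.angles <- function(x, ...) {
  unit <- attr(x, "unit_hint")
  cat(sprintf("Angle sample: n = %d (stored in radians, input unit: %s)\n",
              length(x), unit))
  print(unclass(x), ...)
  invisible(x)
}

# keep the class through subsetting
#' @export
`[.angles` <- function(x, i) {
  structure(unclass(x)[i], unit_hint = attr(x, "unit_hint"), class = "angles")
}

unit_hint <- function(x) {
  u <- attr(x, "unit_hint")
  if (is.null(u)) "radians" else u
}

#' Convert between degrees and radians
#'
#' @param x numeric vector of angles.
#' @return `rad2deg(x)` in degrees; `deg2rad(x)` in radians.
#' @export
rad2deg <- function(x) x * 180 / pi

#' @rdname rad2deg
#' @export
deg2rad <- function(x) x * pi / 180

#' Read an angle file
#'
#' Reads one angle per line (or a single-column CSV). Lines starting with `#`
#' and blank lines are ignored. Any other line that does not parse as a single
#' number is a hard error naming the offending line.
#'
#' @param path file path.
#' @param unit unit the file is written in: `"degrees"` (the field's common
#'   convention, default) or `"radians"`.
#' @return An [angles] object.
#' @export
read_angles <- function(path, unit = c("degrees", "radians")) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(sub(",\\s*$", "", trimws(lines[keep]))))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value at line %d of '%s': \"%s\"",
                 idx[bad[1L]], path, lines[idx[bad[1L]]]), call. = FALSE)
  }
  if (length(vals) == 0L) {
    stop(sprintf("no angles found in '%s'", path), call. = FALSE)
  }
  angles(vals, unit = unit)
}

#' Write an angle file
#'
#' Writes one angle per line in the requested unit. Fifteen significant
#' digits are printed so a write/read round trip reproduces the sample to
#' better than 1e-12 radians in either unit.
#'
#' @param x an [angles] object or numeric vector of radians.
#' @param path output file path.
#' @param unit unit to write: `"degrees"` (default) or `"radians"`.
#' @export
write_angles <- function(x, path, unit = c("degrees", "radians")) {
  unit <- match.arg(unit)
  x <- as_angles(x)
  v <- if (unit == "degrees") rad2deg(as.numeric(x)) else as.numeric(x)
  writeLines(formatC(v, digits = 15, format = "g"), path)
  invisible(path)
}
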