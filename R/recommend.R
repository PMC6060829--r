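#' Which uniformity test should I use?
#'
#' Maps the shape of the departure a researcher expects to the test the
#' simulation study supports, with the caveats that go with it:
#' \describe{
#'   \item{unimodal, direction known a priori}{V-test. A significant V-test
#'     must always be interpreted together with a confidence interval for the
#'     population mean direction ([mean_direction_ci()]): the test alone does
#'     not show concentration around the specified direction.}
#'   \item{unimodal, no expected direction}{Rayleigh test.}
#'   \item{multimodal, f modes mirrored around the circle}{Rayleigh test
#'     after the f-fold transformation ([ffold_transform()]); f must be fixed
#'     on or before data inspection or type-I error is inflated.}
#'   \item{multimodal, symmetry unknown}{Hermans-Rasson test.}
#' }
#'
#' @param expected_shape one of `"unimodal_with_direction"`,
#'   `"unimodal_no_direction"`, `"multimodal_mirrored"`,
#'   `"multimodal_unknown_symmetry"`.
#' @param f number of mirrored modes; required for `"multimodal_mirrored"`.
#' @return A list of class `"circ_recommendation"` with `expected_shape`,
#'   `recommended_test`, `f`, and `caveats`.
#' @examples
#' recommend("multimodal_unknown_symmetry")
#' recommend("multimodal_mirrored", f = 2)
#' @export
recommend <- function(expected_shape = c("unimodal_with_direction",
                                         "unimodal_no_direction",
                                         "multimodal_mirrored",
                                         "multimodal_unknown_symmetry"),
                      f = NULL) {
  expected_shape <- match.arg(expected_shape)
  out <- switch(expected_shape,
    unimodal_with_direction = list(
      recommended_test = "V-test",
      caveats = paste("The expected direction must be set a priori, before any",
                      "inspection of the data. A significant V-test must always",
                      "be interpreted in combination with a confidence interval",
                      "for the population mean direction; only a narrow interval",
                      "containing the pre-specified direction supports the",
                      "directional hypothesis.")),
    unimodal_no_direction = list(
      recommended_test = "Rayleigh test",
      caveats = paste("Most powerful against unimodal (von Mises-like)",
                      "departures; very low power against multimodal ones.")),
    multimodal_mirrored = {
      if (is.null(f)) {
        stop("'f' (the number of mirrored modes) is required for the",
             " multimodal_mirrored shape", call. = FALSE)
      }
      list(recommended_test =
             sprintf("Rayleigh test after %d-fold transformation", as.integer(f)),
           caveats = paste("The fold number f has to be decided on or before",
                           "data inspection; choosing it after seeing the data",
                           "inflates the type-I error rate. Requires modes of",
                           "equal size, mirrored around the circle, each locally",
                           "symmetric."))
    },
    multimodal_unknown_symmetry = list(
      recommended_test = "Hermans-Rasson test",
      caveats = paste("Best all-round power across multimodal departures;",
                      "expect low absolute power when many modes are perfectly",
                      "mirrored and samples are small.")))
  structure(c(list(expected_shape = expected_shape,
                   f = if (is.null(f)) NA_integer_ else as.integer(f)), out),
            class = "circ_recommendation")
}

#' @export
print.circ_recommendation <- function(x, ...) {
  cat(sprintf("Expected distribution: %s\n", x$expected_shape))
  cat(sprintf("Recommended test:      %s\n", x$recommended_test))
  cat(strwrap(paste("Caveats:", x$caveats), width = 76, exdent = 2), sep = "\n")
  invisible(x)
}
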