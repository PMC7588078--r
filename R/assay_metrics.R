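#' Percent-of-control normalization for batched validation assays
#'
#' The batch normalization of the individual retest assays: the mean of the
#' control-sgRNA measurements is set to 100% and every test measurement is
#' expressed relative to it, `100 * test / mean(controls)`. Jointly
#' rescaling controls and tests leaves the result unchanged.
#'
#' @param test_values Numeric vector of test measurements (named or not).
#' @param control_values Numeric vector of control measurements (typically
#'   the two control sgRNAs of the batch); their mean must be positive.
#' @return A tibble with `sample` and `percent_of_control`.
#' @export
#' @examples
#' percent_of_control(c(sgA = 50, sgB = 200), control_values = c(80, 120))
percent_of_control <- function(test_values, control_values) {
  ctrl <- mean(control_values)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop_sortscreen("control mean must be positive",
                    class = "sortscreen_config_error")
  }
  nm <- names(test_values)
  if (is.null(nm)) nm <- as.character(seq_along(test_values))
  tibble(sample = nm,
         percent_of_control = 100 * unname(test_values) / ctrl)
}

#' Percent of internalized receptors
#'
#' Agonist-induced receptor internalization from surface labeling:
#' `100 - 100 * surface_after / surface_before`. Equal before/after surface
#' signal gives 0%; complete loss of surface receptor gives 100%.
#'
#' @param surface_before Surface signal before agonist (positive).
#' @param surface_after Surface signal after agonist (non-negative);
#'   vectorized.
#' @return Percent internalized (<= 100; negative when surface levels rose).
#' @export
#' @examples
#' percent_internalized(100, 80)  # 20
percent_internalized <- function(surface_before, surface_after) {
  if (any(surface_before <= 0)) {
    stop_sortscreen("surface_before must be positive",
                    class = "sortscreen_config_error")
  }
  if (any(surface_after < 0)) {
    stop_sortscreen("surface_after must be non-negative",
                    class = "sortscreen_config_error")
  }
  100 - (surface_after / surface_before) * 100
}

#' Normalize a firefly biosensor time course to its Renilla control
#'
#' Dual-luciferase normalization for the real-time cAMP biosensor:
#' elementwise division of the firefly time course by the constitutive
#' Renilla signal, which controls for transfection efficiency.
#'
#' @param firefly_timecourse Numeric vector of firefly luminescence values.
#' @param renilla Single positive Renilla luminescence value.
#' @return The normalized time course.
#' @export
#' @examples
#' normalize_biosensor(c(2, 4, 6), renilla = 2)
normalize_biosensor <- function(firefly_timecourse, renilla) {
  if (length(renilla) != 1 || !is.finite(renilla) || renilla <= 0) {
    stop_sortscreen("renilla must be a single positive value",
                    class = "sortscreen_config_error")
  }
  firefly_timecourse / renilla
}
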