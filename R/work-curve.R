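#' Construct a steered-pulling work curve
#'
#' A work curve is one constant-velocity pull: the accumulated pulling work
#' sampled along the reaction coordinate `xi` (the distance between the
#' nanosheet central plane and the adsorbate centre of mass, in angstrom),
#' together with the pulling protocol metadata. Adsorption pulls move the
#' harmonic trap from the water bulk toward the surface (`xi` strictly
#' decreasing); desorption pulls move it the other way (`xi` strictly
#' increasing). Work starts at zero by construction.
#'
#' @param xi Reaction-coordinate samples (angstrom), strictly monotone.
#' @param work Accumulated pulling work at each sample (kJ/mol); `work[1]`
#'   must be 0.
#' @param direction `"adsorption"` (xi decreasing) or `"desorption"`
#'   (xi increasing).
#' @param temperature Bath temperature in kelvin (default 310, human body
#'   temperature).
#' @param spring_k Stiffness of the virtual spring, kJ/(mol A^2)
#'   (default 1000).
#' @param velocity Trap speed, A/ps (default 1e-4).
#' @param time Optional time stamps in ps (defaults to
#'   `|xi - xi[1]| / velocity`).
#' @param label Free-text label, e.g. which nanosheet face the pull probed.
#'
#' @return A tibble of class `work_curve` with columns `time`, `xi`, `work`
#'   and attributes `direction`, `temperature`, `spring_k`, `velocity`,
#'   `label`.
#' @examples
#' work_curve(xi = c(10, 6, 2), work = c(0, -5, -20), direction = "adsorption")
#' @export
work_curve <- function(xi, work, direction = c("adsorption", "desorption"),
                       temperature = 310, spring_k = 1000, velocity = 1e-4,
                       time = NULL, label = "") {
  direction <- match.arg(direction)
  xi <- as.double(xi)
  work <- as.double(work)
  if (length(xi) != length(work)) {
    abort("`xi` and `work` must have the same length.", class = "cin2d_malformed_curve")
  }
  if (length(xi) < 2) {
    abort("A work curve needs at least 2 samples.", class = "cin2d_malformed_curve")
  }
  if (anyNA(xi) || anyNA(work)) {
    abort("`xi` and `work` must be finite.", class = "cin2d_malformed_curve")
  }
  d <- diff(xi)
  if (direction == "adsorption" && !all(d < 0)) {
    abort("Adsorption pulls must have strictly decreasing `xi`.",
          class = "cin2d_malformed_curve")
  }
  if (direction == "desorption" && !all(d > 0)) {
    abort("Desorption pulls must have strictly increasing `xi`.",
          class = "cin2d_malformed_curve")
  }
  if (abs(work[1]) > 1e-9) {
    abort("Accumulated work must start at 0.", class = "cin2d_malformed_curve")
  }
  stopifnot(temperature > 0, spring_k > 0, velocity > 0)
  if (is.null(time)) time <- abs(xi - xi[1]) / velocity
  out <- new_tibble(
    list(time = as.double(time), xi = xi, work = work),
    nrow = length(xi),
    class = "work_curve"
  )
  attr(out, "direction") <- direction
  attr(out, "temperature") <- as.double(temperature)
  attr(out, "spring_k") <- as.double(spring_k)
  attr(out, "velocity") <- as.double(velocity)
  attr(out, "label") <- as.character(label)
  out
}

#' @export
print.work_curve <- function(x, ...) {
  cat(sprintf(
    "<work_curve> %s pull, %d samples, xi in [%.3g, %.3g] A, T = %g K, k = %g kJ/(mol A^2), v = %g A/ps\n",
    curve_direction(x), nrow(x), min(x$xi), max(x$xi),
    attr(x, "temperature"), attr(x, "spring_k"), attr(x, "velocity")
  ))
  NextMethod()
}

#' Pull direction of a work curve
#' @param curve A [work_curve()].
#' @return `"adsorption"` or `"desorption"`.
#' @export
curve_direction <- function(curve) {
  attr(curve, "direction")
}

is_work_curve <- function(x) inherits(x, "work_curve")

assert_work_curve <- function(curve, direction = NULL) {
  if (!is_work_curve(curve)) {
    abort("Expected a `work_curve` object.", class = "cin2d_type_error")
  }
  if (!is.null(direction) && !identical(curve_direction(curve), direction)) {
    abort(sprintf("Expected a %s pull, got a %s pull.", direction,
                  curve_direction(curve)),
          class = "cin2d_direction_error")
  }
  invisible(curve)
}

# Normalise the `curves` argument of the multi-curve estimators: a bare
# work_curve becomes a one-element list.
as_curve_list <- function(curves) {
  if (is_work_curve(curves)) curves <- list(curves)
  if (!is.list(curves) || length(curves) == 0 ||
      !all(vapply(curves, is_work_curve, logical(1)))) {
    abort("Expected a work_curve or a non-empty list of work_curve objects.",
          class = "cin2d_estimation_error")
  }
  curves
}
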