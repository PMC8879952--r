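#' Construct a free-energy profile
#'
#' A free-energy change profile \eqn{\Delta G(\xi)} on an increasing
#' reaction-coordinate grid, zero-referenced at the unbound (largest-`xi`)
#' end, with a per-point dispersion corridor and the number of pulling
#' curves that contributed.
#'
#' @param xi Increasing coordinate grid (angstrom).
#' @param dG Free-energy change at each grid point (kJ/mol); the value at
#'   the largest `xi` must be 0 (use [rezero_profile()] to enforce it).
#' @param sd Per-point standard deviation (kJ/mol, non-negative). All zero
#'   when a single curve contributed.
#' @param n_replicates Number of contributing work curves.
#' @param estimator Free-text name of the estimator that produced the
#'   profile.
#' @param temperature Temperature in kelvin carried over from the pulls.
#'
#' @return A tibble of class `free_energy_profile` with columns `xi`, `dG`,
#'   `sd` and attributes `n_replicates`, `estimator`, `temperature`.
#' @export
free_energy_profile <- function(xi, dG, sd = 0, n_replicates = 1L,
                                estimator = "manual", temperature = 310) {
  xi <- as.double(xi)
  dG <- as.double(dG)
  sd <- rep_len(as.double(sd), length(xi))
  if (length(xi) != length(dG) || length(xi) < 2) {
    abort("`xi` and `dG` must have equal length >= 2.",
          class = "cin2d_invalid_profile")
  }
  if (!all(diff(xi) > 0)) {
    abort("Profile grid must be strictly increasing.",
          class = "cin2d_invalid_profile")
  }
  if (any(sd < 0, na.rm = TRUE)) {
    abort("`sd` must be non-negative.", class = "cin2d_invalid_profile")
  }
  out <- new_tibble(
    list(xi = xi, dG = dG, sd = sd),
    nrow = length(xi),
    class = "free_energy_profile"
  )
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "estimator") <- estimator
  attr(out, "temperature") <- as.double(temperature)
  out
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile> %d points, xi in [%.3g, %.3g] A, min dG = %.3g kJ/mol, %d replicate(s), estimator: %s\n",
    nrow(x), min(x$xi), max(x$xi), min(x$dG),
    attr(x, "n_replicates"), attr(x, "estimator")
  ))
  NextMethod()
}

#' Re-reference a profile to zero at its unbound end
#'
#' Subtracts the value at the largest-`xi` grid point, the water-bulk
#' reference where the free-energy change is zero by definition.
#' Idempotent: applying it twice changes nothing.
#'
#' @param profile A [free_energy_profile()].
#' @return The profile with `dG[length(dG)] == 0`.
#' @export
rezero_profile <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  profile$dG <- profile$dG - profile$dG[nrow(profile)]
  profile
}

#' Free-energy profile from a single forced-adsorption pull
#'
#' Stiff-spring estimate: at slow pulling with a stiff spring the
#' accumulated work approximates the free-energy change along the reaction
#' coordinate, \eqn{\Delta G(\xi) \approx W_{fwd}(\xi)}. The curve is
#' reordered onto an increasing grid and re-zeroed at the bulk end.
#'
#' @param curve A [work_curve()] with direction `"adsorption"`.
#' @return A [free_energy_profile()] with `sd = 0`, one replicate.
#' @examples
#' wc <- work_curve(c(10, 6, 2), c(0, -5, -20), "adsorption")
#' pmf_forward(wc)
#' @export
pmf_forward <- function(curve) {
  assert_work_curve(curve, "adsorption")
  ord <- order(curve$xi)
  rezero_profile(free_energy_profile(
    xi = curve$xi[ord], dG = curve$work[ord], sd = 0, n_replicates = 1L,
    estimator = "forward-work", temperature = attr(curve, "temperature")
  ))
}

#' Free-energy profile from a single forced-desorption pull
#'
#' The reverse-pull counterpart of [pmf_forward()]: the work still to be
#' spent from `xi` to the bulk endpoint, negated,
#' \eqn{\Delta G(\xi) = -(W_{rev}(\xi_{end}) - W_{rev}(\xi))}, so that the
#' profile is again zero at the unbound end.
#'
#' @param curve A [work_curve()] with direction `"desorption"`.
#' @return A [free_energy_profile()] with `sd = 0`, one replicate.
#' @examples
#' wc <- work_curve(c(2, 6, 10), c(0, 15, 20), "desorption")
#' pmf_reverse(wc)
#' @export
pmf_reverse <- function(curve) {
  assert_work_curve(curve, "desorption")
  dG <- curve$work - curve$work[nrow(curve)]
  rezero_profile(free_energy_profile(
    xi = curve$xi, dG = dG, sd = 0, n_replicates = 1L,
    estimator = "reverse-work", temperature = attr(curve, "temperature")
  ))
}

# Unidirectional profile matching the curve's own direction.
curve_profile <- function(curve) {
  switch(curve_direction(curve),
         adsorption = pmf_forward(curve),
         desorption = pmf_reverse(curve))
}

# Intersection grid of a set of curves/profiles at the coarsest native
# spacing (no invented smoothness). `dx` overrides the spacing.
common_grid <- function(xi_list, dx = NULL) {
  lo <- max(vapply(xi_list, min, double(1)))
  hi <- min(vapply(xi_list, max, double(1)))
  if (!(hi > lo)) {
    abort("Input curves have no overlapping coordinate range.",
          class = "cin2d_estimation_error")
  }
  if (is.null(dx)) {
    dx <- max(vapply(xi_list, function(x) mean(abs(diff(sort(x)))), double(1)))
  }
  n <- max(2L, floor((hi - lo) / dx) + 1L)
  seq(lo, hi, length.out = n)
}

check_consistent_temperature <- function(curves) {
  temps <- vapply(curves, function(c) attr(c, "temperature"), double(1))
  if (diff(range(temps)) > 1e-6 * mean(temps)) {
    abort("Curves carry inconsistent temperature metadata.",
          class = "cin2d_estimation_error")
  }
  temps[1]
}

#' Bidirectional free-energy profile from paired pulls
#'
#' Each curve is converted with the matching unidirectional estimator
#' ([pmf_forward()] or [pmf_reverse()]), interpolated onto the intersection
#' grid, and averaged pointwise; to first order the dissipation of forward
#' and reverse pulls cancels in the mean, which converges faster than a
#' unidirectional average. The dispersion corridor is the pointwise sample
#' standard deviation over curves.
#'
#' @param curves A list of [work_curve()] objects containing at least one
#'   adsorption and one desorption pull with overlapping `xi` ranges and
#'   consistent temperatures.
#' @param dx Optional resampling grid spacing (angstrom); defaults to the
#'   coarsest native spacing among the inputs.
#' @return A [free_energy_profile()] re-zeroed at the unbound end, with
#'   `n_replicates = length(curves)`.
#' @export
pmf_bidirectional <- function(curves, dx = NULL) {
  curves <- as_curve_list(curves)
  dirs <- vapply(curves, curve_direction, character(1))
  if (!any(dirs == "adsorption") || !any(dirs == "desorption")) {
    abort("Bidirectional estimation needs at least one adsorption and one desorption pull.",
          class = "cin2d_estimation_error")
  }
  temperature <- check_consistent_temperature(curves)
  profs <- lapply(curves, curve_profile)
  grid <- common_grid(lapply(profs, `[[`, "xi"), dx = dx)
  mat <- vapply(profs, function(p) approx(p$xi, p$dG, xout = grid)$y,
                double(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  dG <- rowMeans(mat)
  sds <- if (ncol(mat) > 1) apply(mat, 1, sd) else rep(0, length(grid))
  rezero_profile(free_energy_profile(
    xi = grid, dG = dG, sd = sds, n_replicates = length(curves),
    estimator = "bidirectional", temperature = temperature
  ))
}

#' Plain mean-work free-energy profile
#'
#' Pointwise mean of the unidirectional work profiles of a set of
#' same-direction pulls. By the second law the mean work overestimates the
#' free-energy change (dissipation is non-negative on average), so this
#' estimator is biased for fast pulls; it serves as the baseline the
#' Jarzynski estimator is compared against.
#'
#' @inheritParams pmf_bidirectional
#' @return A [free_energy_profile()] re-zeroed at the unbound end.
#' @export
pmf_mean_work <- function(curves, dx = NULL) {
  curves <- as_curve_list(curves)
  dirs <- unique(vapply(curves, curve_direction, character(1)))
  if (length(dirs) != 1) {
    abort("Mean-work estimation needs same-direction curves.",
          class = "cin2d_estimation_error")
  }
  temperature <- check_consistent_temperature(curves)
  profs <- lapply(curves, curve_profile)
  grid <- common_grid(lapply(profs, `[[`, "xi"), dx = dx)
  mat <- vapply(profs, function(p) approx(p$xi, p$dG, xout = grid)$y,
                double(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  sds <- if (ncol(mat) > 1) apply(mat, 1, sd) else rep(0, length(grid))
  rezero_profile(free_energy_profile(
    xi = grid, dG = rowMeans(mat), sd = sds, n_replicates = length(curves),
    estimator = "mean-work", temperature = temperature
  ))
}

# log(mean(exp(x))) with the largest exponent factored out, to keep the
# exponential work average finite for strongly dissipative pulls.
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski free-energy profile from repeated same-direction pulls
#'
#' Nonequilibrium work estimator
#' \eqn{\Delta G(\xi) = -k_B T \ln \langle e^{-W(\xi)/k_B T} \rangle}
#' over repeated pulls, evaluated pointwise on the intersection grid with
#' the largest exponent factored out of the exponential average. More
#' accurate than the plain work mean when pulls are fast enough to
#' dissipate, at the cost of needing more trajectories. The dispersion
#' corridor is a bootstrap standard deviation over curves.
#'
#' @param curves A list of at least two same-direction [work_curve()]
#'   objects with overlapping ranges.
#' @param temperature Temperature in kelvin; defaults to the (consistent)
#'   curve metadata.
#' @param n_boot Bootstrap replicates for the dispersion corridor
#'   (resampling curves with replacement).
#' @param seed Optional integer seed for the bootstrap.
#' @param dx Optional resampling grid spacing (angstrom).
#' @return A [free_energy_profile()] re-zeroed at the unbound end.
#' @export
pmf_jarzynski <- function(curves, temperature = NULL, n_boot = 200,
                          seed = NULL, dx = NULL) {
  curves <- as_curve_list(curves)
  if (length(curves) < 2) {
    abort("Jarzynski estimation needs at least 2 curves.",
          class = "cin2d_insufficient_sample")
  }
  dirs <- unique(vapply(curves, curve_direction, character(1)))
  if (length(dirs) != 1) {
    abort("Jarzynski estimation needs same-direction curves.",
          class = "cin2d_estimation_error")
  }
  if (is.null(temperature)) temperature <- check_consistent_temperature(curves)
  beta <- 1 / thermal_energy(temperature)

  profs <- lapply(curves, function(c) {
    ord <- order(c$xi)
    list(xi = c$xi[ord], w = c$work[ord])
  })
  grid <- common_grid(lapply(profs, `[[`, "xi"), dx = dx)
  wmat <- vapply(profs, function(p) approx(p$xi, p$w, xout = grid)$y,
                 double(length(grid)))
  wmat <- matrix(wmat, nrow = length(grid))

  # The exponential average applies to either direction: it estimates the
  # free energy relative to each pull's own start, and the final re-zero
  # shifts the reference to the bulk end.
  jarz <- function(cols) {
    est <- -apply(-beta * wmat[, cols, drop = FALSE], 1, log_mean_exp) / beta
    est - est[length(est)]
  }
  dG <- jarz(seq_along(curves))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  boot <- replicate(n_boot,
                    jarz(sample.int(length(curves), replace = TRUE)))
  sds <- apply(boot, 1, sd)
  rezero_profile(free_energy_profile(
    xi = grid, dG = dG, sd = sds, n_replicates = length(curves),
    estimator = "jarzynski", temperature = temperature
  ))
}

#' @rdname autoplot.free_energy_profile
#' @export
plot_profile <- function(profile, ...) {
  ggplot2::autoplot(profile, ...)
}

#' Plot a free-energy profile with its dispersion corridor
#'
#' @param object,profile A [free_energy_profile()].
#' @param ... Unused.
#' @return A ggplot object: \eqn{\Delta G(\xi)} with a +/- 1 sd ribbon.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$xi, y = .data$dG)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$dG - .data$sd,
                                      ymax = .data$dG + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(xi ~ (ring(A))),
                  y = expression(Delta * G ~ (kJ/mol)))
}
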