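#' Parametric 1-D model potentials for synthetic pulling
#'
#' Free-energy landscapes with known ground truth, used by the Langevin
#' pulling simulator to generate work-curve fixtures:
#' \describe{
#'   \item{`flat`}{no mean force anywhere.}
#'   \item{`adsorption_well`}{a Gaussian adsorption well of depth
#'     `well_depth` (< 0) at `well_position`, plus a steep exponential
#'     repulsive wall below `wall_position` standing in for the excluded
#'     volume of the nanosheet; the potential decays to 0 in the bulk.}
#'   \item{`hydration_oscillatory`}{the adsorption well modulated by a
#'     damped cosine (`osc_amplitude`, `osc_period`) emulating the layered
#'     hydration shells that put secondary minima into profiles of strongly
#'     hydrophilic sheets.}
#'   \item{`extraction_plateau`}{a smooth nondecreasing ramp from 0 to
#'     `plateau_height` (> 0), the shape of a lipid-extraction landscape.}
#' }
#'
#' @param kind Potential family, see above.
#' @param well_depth Depth of the adsorption well, kJ/mol (<= 0).
#' @param well_position,well_width Centre and Gaussian width of the well,
#'   angstrom.
#' @param wall_position,wall_steepness,wall_height Repulsive wall:
#'   `wall_height * exp(-(xi - wall_position) * wall_steepness)`.
#' @param osc_amplitude,osc_period Hydration-layer modulation, kJ/mol and
#'   angstrom.
#' @param plateau_height Extraction plateau, kJ/mol (> 0).
#' @param ramp_start,ramp_width Onset and length of the extraction ramp,
#'   angstrom.
#' @return An object of class `model_potential` with evaluators `U(xi)` and
#'   `dU(xi)` (kJ/mol and kJ/mol/A).
#' @examples
#' pot <- model_potential("adsorption_well", well_depth = -50)
#' pot$U(c(2, 4, 12))
#' @export
model_potential <- function(kind = c("adsorption_well", "hydration_oscillatory",
                                     "extraction_plateau", "flat"),
                            well_depth = -50, well_position = 4,
                            well_width = 1, wall_position = 1.5,
                            wall_steepness = 3, wall_height = 100,
                            osc_amplitude = 0, osc_period = 3,
                            plateau_height = NULL,
                            ramp_start = 1, ramp_width = 6) {
  kind <- match.arg(kind)
  if (kind %in% c("adsorption_well", "hydration_oscillatory") && well_depth > 0) {
    abort("`well_depth` must be <= 0 for a well.", class = "cin2d_parameter_error")
  }
  if (kind == "extraction_plateau") {
    if (is.null(plateau_height) || plateau_height <= 0) {
      abort("`plateau_height` must be positive for an extraction landscape.",
            class = "cin2d_parameter_error")
    }
  } else {
    plateau_height <- 0
  }
  params <- c(well_depth, well_position, well_width, wall_position,
              wall_steepness, wall_height, osc_amplitude, osc_period,
              plateau_height, 0)
  if (kind == "extraction_plateau") {
    params[2] <- ramp_start
    params[3] <- ramp_width
  }
  code <- match(kind, c("flat", "adsorption_well", "hydration_oscillatory",
                        "extraction_plateau")) - 1L
  structure(
    list(
      kind = kind,
      code = code,
      params = params,
      U = function(xi) cpp_potential(code, params, as.double(xi), FALSE),
      dU = function(xi) cpp_potential(code, params, as.double(xi), TRUE)
    ),
    class = "model_potential"
  )
}

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("<model_potential> kind: %s\n", x$kind))
  invisible(x)
}

#' Ground-truth minimum of a model potential
#'
#' Numerically locates the global minimum of `U` over `[lower, upper]`
#' (grid scan refined by golden-section search). This is the oracle the
#' profile estimators are checked against.
#'
#' @param potential A [model_potential()].
#' @param lower,upper Search interval, angstrom.
#' @return A list with `xi_min` and `U_min`.
#' @export
potential_minimum <- function(potential, lower = 0.5, upper = 15) {
  grid <- seq(lower, upper, length.out = 2001)
  u <- potential$U(grid)
  i <- which.min(u)
  span <- c(grid[max(1, i - 2)], grid[min(length(grid), i + 2)])
  opt <- optimize(function(x) potential$U(x), interval = span)
  list(xi_min = opt$minimum, U_min = opt$objective)
}

#' Constant-velocity pulling protocol
#'
#' Protocol metadata for one steered pull: the harmonic trap of stiffness
#' `spring_k` moves from `xi_start` to `xi_end` at constant `velocity`.
#' Defaults follow the rapid-assessment steered-MD protocol: spring
#' 1000 kJ/(mol A^2), velocity 1e-4 A/ps, 310 K. The friction sets the
#' surrogate's time scale and is chosen so that slow pulls finish in
#' seconds of CPU time; the integration step must resolve the trap
#' relaxation time `friction / spring_k` (error if
#' `dt > 0.1 * friction / spring_k`).
#'
#' @param xi_start,xi_end Trap path, angstrom. `xi_start > xi_end` is an
#'   adsorption pull (bulk toward surface), the opposite a desorption pull.
#' @param spring_k Trap stiffness, kJ/(mol A^2).
#' @param velocity Trap speed, A/ps (> 0).
#' @param temperature Bath temperature, K.
#' @param friction Friction coefficient `gamma`, kJ ps/(mol A^2).
#' @param dt Integration step, ps; default `0.05 * friction / spring_k`.
#' @param seed Optional integer seed.
#' @param burn_in Equilibration steps at the stationary trap before the
#'   pull starts.
#' @return A list of class `pull_protocol`.
#' @export
pull_protocol <- function(xi_start, xi_end, spring_k = 1000, velocity = 1e-4,
                          temperature = 310, friction = 50, dt = NULL,
                          seed = NULL, burn_in = 0L) {
  stopifnot(spring_k > 0, velocity > 0, temperature > 0, friction > 0)
  if (abs(xi_end - xi_start) <= 0) {
    abort("`xi_start` and `xi_end` must differ.", class = "cin2d_parameter_error")
  }
  relax <- friction / spring_k
  if (is.null(dt)) dt <- 0.05 * relax
  if (dt <= 0 || dt > 0.1 * relax) {
    abort(sprintf(
      "dt = %g ps under-resolves the trap relaxation time (limit %.3g ps).",
      dt, 0.1 * relax), class = "cin2d_stability_error")
  }
  structure(
    list(xi_start = xi_start, xi_end = xi_end, spring_k = spring_k,
         velocity = velocity, temperature = temperature, friction = friction,
         dt = dt, seed = seed, burn_in = as.integer(burn_in),
         direction = if (xi_end < xi_start) "adsorption" else "desorption"),
    class = "pull_protocol"
  )
}

#' Simulate one steered pull over a model potential
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' `dxi = [-U'(xi) - k (xi - lambda(t))] / gamma dt + sqrt(2 kB T dt / gamma) eta`
#' with the trap centre `lambda(t)` moving at constant velocity, and
#' external work accumulated as `dW = k (lambda - xi) dlambda`. The output
#' is sampled on a uniform trap-position grid. Reproducible under a fixed
#' protocol seed.
#'
#' @param potential A [model_potential()].
#' @param protocol A [pull_protocol()].
#' @param n_out Number of saved samples along the pull.
#' @param label Label stored on the resulting curve.
#' @return A [work_curve()] whose `xi` column is the trap position, with a
#'   `force` attribute holding the instantaneous spring force at each
#'   sample (used by the force-dialect writer).
#' @export
simulate_pull <- function(potential, protocol, n_out = 201, label = "") {
  stopifnot(inherits(potential, "model_potential"),
            inherits(protocol, "pull_protocol"))
  n_steps <- max(n_out, ceiling(abs(protocol$xi_end - protocol$xi_start) /
                                  (protocol$velocity * protocol$dt)))
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  res <- cpp_simulate_pull(
    potential$code, potential$params, protocol$spring_k, protocol$friction,
    thermal_energy(protocol$temperature), protocol$dt,
    protocol$xi_start, protocol$xi_end, as.integer(n_steps),
    as.integer(n_out), protocol$burn_in
  )
  out <- work_curve(
    xi = res$lambda, work = res$work, direction = protocol$direction,
    temperature = protocol$temperature, spring_k = protocol$spring_k,
    velocity = protocol$velocity,
    time = seq(0, abs(protocol$xi_end - protocol$xi_start) / protocol$velocity,
               length.out = n_out),
    label = label
  )
  attr(out, "force") <- res$force
  out
}

#' Generate a bidirectional set of pulls
#'
#' Runs `n_forward` forced-adsorption and `n_reverse` forced-desorption
#' pulls over the same potential. Per-pull seeds are derived
#' deterministically from the master seed; each desorption pull starts
#' from a bound state equilibrated by a fixed 1e4-step burn-in at the
#' stationary trap.
#'
#' @param potential A [model_potential()].
#' @param protocol A [pull_protocol()] describing the adsorption direction
#'   (`xi_start` in the bulk, `xi_end` near the surface).
#' @param n_forward,n_reverse Number of pulls per direction (>= 1 each).
#' @param seed Master seed for the whole set.
#' @return A list of [work_curve()] objects tagged `forward-i`/`reverse-j`.
#' @export
make_bidirectional_set <- function(potential, protocol, n_forward = 2,
                                   n_reverse = 2, seed = 1) {
  if (n_forward < 1 || n_reverse < 1) {
    abort("A bidirectional set needs at least one pull in each direction.",
          class = "cin2d_parameter_error")
  }
  if (protocol$direction != "adsorption") {
    abort("`protocol` must describe the adsorption direction (xi_start > xi_end).",
          class = "cin2d_parameter_error")
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_forward + n_reverse)
  fwd <- lapply(seq_len(n_forward), function(i) {
    p <- protocol
    p$seed <- seeds[i]
    simulate_pull(potential, p, label = sprintf("forward-%d", i))
  })
  rev <- lapply(seq_len(n_reverse), function(i) {
    p <- protocol
    p$xi_start <- protocol$xi_end
    p$xi_end <- protocol$xi_start
    p$direction <- "desorption"
    p$seed <- seeds[n_forward + i]
    p$burn_in <- 10000L
    simulate_pull(potential, p, label = sprintf("reverse-%d", i))
  })
  c(fwd, rev)
}

#' Sample the equilibrium distribution at a stationary trap
#'
#' Runs the same integrator with zero trap velocity and returns thinned
#' particle positions; the stationary law is the Boltzmann distribution of
#' `U(xi) + spring_k / 2 * (xi - at)^2`. Used to validate the sampler.
#'
#' @param potential A [model_potential()].
#' @param at Trap position, angstrom.
#' @param n_samples,thin,burn_in Sampling schedule (steps).
#' @param spring_k,temperature,friction,dt,seed As in [pull_protocol()].
#' @return A numeric vector of positions.
#' @export
sample_equilibrium <- function(potential, at, n_samples = 2000, thin = 20,
                               burn_in = 10000, spring_k = 1000,
                               temperature = 310, friction = 50, dt = NULL,
                               seed = NULL) {
  if (is.null(dt)) dt <- 0.05 * friction / spring_k
  if (!is.null(seed)) set.seed(seed)
  cpp_sample_fixed(potential$code, potential$params, spring_k, friction,
                   thermal_energy(temperature), dt, at,
                   as.integer(n_samples), as.integer(thin),
                   as.integer(burn_in))
}

#' Synthetic lipid-extraction profiles with known plateaus
#'
#' Builds smooth monotone extraction free-energy profiles rising from 0 to
#' a plateau of `n * per_lipid` kJ/mol for each group size, optionally with
#' additive Gaussian noise, mimicking the shape of collective
#' lipid-extraction landscapes whose right-hand plateaus encode the
#' per-lipid barriers.
#'
#' @param barriers A data frame with columns `n` (group size) and
#'   `per_lipid` (barrier per lipid, kJ/mol, > 0).
#' @param noise_sd Additive Gaussian noise, kJ/mol.
#' @param seed Optional seed for the noise.
#' @param xi_max,n_points Grid extent (angstrom) and resolution.
#' @return A named list of [free_energy_profile()] objects (`"N1"`,
#'   `"N2"`, ...), each suitable for [extraction_barrier()].
#' @examples
#' profs <- make_extraction_fixture(data.frame(n = 1, per_lipid = 93.3))
#' extraction_barrier(profs$N1, 1)
#' @export
make_extraction_fixture <- function(barriers, noise_sd = 0, seed = NULL,
                                    xi_max = 30, n_points = 121) {
  barriers <- as_tibble(barriers)
  stopifnot(all(c("n", "per_lipid") %in% names(barriers)))
  if (any(barriers$per_lipid <= 0)) {
    abort("Per-lipid barriers must be positive.", class = "cin2d_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  xi <- seq(0, xi_max, length.out = n_points)
  t <- pmin(pmax(xi / (0.6 * xi_max), 0), 1)
  ramp <- t^2 * (3 - 2 * t)
  out <- lapply(seq_len(nrow(barriers)), function(i) {
    plateau <- barriers$n[i] * barriers$per_lipid[i]
    dG <- plateau * ramp
    if (noise_sd > 0) {
      dG <- dG + c(0, stats::rnorm(n_points - 1, sd = noise_sd))
    }
    free_energy_profile(xi = xi, dG = dG, sd = noise_sd,
                        n_replicates = 1L,
                        estimator = "extraction-fixture")
  })
  names(out) <- paste0("N", barriers$n)
  out
}
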