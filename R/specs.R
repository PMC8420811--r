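#' Physical ball specification
#'
#' Describes the ball being tracked: its radius (and hence the physical
#' diameter `size = 2 * radius` that the size prior refers to), the drag
#' coefficient used when aerodynamic drag is simulated, and its mass.
#' The frontal cross-section `pi * radius^2` is derived and stored.
#'
#' @param radius Ball radius in metres. Must be positive.
#' @param drag_coefficient Dimensionless drag coefficient (>= 0). Only used
#'   by [simulate_drag()].
#' @param mass Ball mass in kg. Must be positive; drag deceleration scales
#'   with `1 / mass`.
#'
#' @return A `ball_spec` list with fields `radius`, `size`,
#'   `drag_coefficient`, `mass` and `cross_section`.
#' @seealso [baseball()], [soccer_ball()]
#' @export
#' @examples
#' ball_spec(radius = 0.037, drag_coefficient = 0.346, mass = 0.145)
ball_spec <- function(radius, drag_coefficient = 0, mass = 0.145) {
  stopifnot(
    is.numeric(radius), length(radius) == 1, is.finite(radius), radius > 0,
    is.numeric(drag_coefficient), length(drag_coefficient) == 1,
    is.finite(drag_coefficient), drag_coefficient >= 0,
    is.numeric(mass), length(mass) == 1, is.finite(mass), mass > 0
  )
  structure(
    list(
      radius = radius,
      size = 2 * radius,
      drag_coefficient = drag_coefficient,
      mass = mass,
      cross_section = pi * radius^2
    ),
    class = "ball_spec"
  )
}

#' Regulation baseball and soccer ball
#'
#' Convenience constructors with regulation dimensions and the drag
#' coefficients commonly used for each ball: a baseball of radius 0.037 m
#' (diameter 0.074 m, mass 0.145 kg, Cd 0.346) and a soccer ball of radius
#' 0.11 m (mass 0.43 kg, Cd 0.4).
#'
#' @param drag_coefficient,mass,radius Overrides for the defaults.
#' @return A [ball_spec()].
#' @export
baseball <- function(drag_coefficient = 0.346, mass = 0.145) {
  ball_spec(radius = 0.037, drag_coefficient = drag_coefficient, mass = mass)
}

#' @rdname baseball
#' @export
soccer_ball <- function(radius = 0.11, drag_coefficient = 0.4, mass = 0.43) {
  ball_spec(radius = radius, drag_coefficient = drag_coefficient, mass = mass)
}

#' Environment specification
#'
#' Gravitational acceleration (downward, positive magnitude) and air density
#' for drag simulations.
#'
#' @param gravity Gravitational acceleration in m/s^2 (> 0). Default is the
#'   standard value 9.807.
#' @param air_density Air density in kg/m^3 (>= 0). Default 1.225 (sea level).
#' @param drag_enabled Logical flag recording whether drag is intended for
#'   this environment; [simulate_drag()] applies drag regardless, the flag is
#'   carried for scenario bookkeeping.
#' @return An `env_spec` list.
#' @export
env_spec <- function(gravity = 9.807, air_density = 1.225,
                     drag_enabled = FALSE) {
  stopifnot(
    is.numeric(gravity), length(gravity) == 1, is.finite(gravity), gravity > 0,
    is.numeric(air_density), length(air_density) == 1,
    is.finite(air_density), air_density >= 0,
    is.logical(drag_enabled), length(drag_enabled) == 1
  )
  structure(
    list(
      gravity = gravity,
      air_density = air_density,
      drag_enabled = drag_enabled
    ),
    class = "env_spec"
  )
}

#' Internalized priors of the GS model
#'
#' The two pieces of contextual knowledge the GS estimator calibrates the
#' optics with: the assumed gravitational acceleration and the assumed
#' physical ball diameter.
#'
#' @param gravity Assumed gravitational acceleration in m/s^2 (> 0).
#' @param size Assumed ball diameter in metres (> 0). Default is a baseball
#'   (0.074 m).
#' @return A `prior_spec` list with fields `gravity` and `size`.
#' @export
prior_spec <- function(gravity = 9.807, size = 0.074) {
  stopifnot(
    is.numeric(gravity), length(gravity) == 1, is.finite(gravity), gravity > 0,
    is.numeric(size), length(size) == 1, is.finite(size), size > 0
  )
  structure(list(gravity = gravity, size = size), class = "prior_spec")
}

#' Weber-noise configuration
#'
#' Weber fractions for the sensory noise injected into each optical variable
#' (`x_chi = x + N(0, x * k_x)`), the fixed Weber fraction assumed for Tau,
#' and the Monte-Carlo settings.
#'
#' @param k_theta,k_gamma,k_gamma_dot Weber fractions (>= 0) for retinal
#'   size, elevation angle and its rate of change. Default 0.05 each.
#' @param k_tau Weber fraction assumed for the Tau cue, default 0.10.
#' @param n_sims Number of Monte-Carlo simulations per condition (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `weber_config` list.
#' @export
weber_config <- function(k_theta = 0.05, k_gamma = 0.05, k_gamma_dot = 0.05,
                         k_tau = 0.10, n_sims = 10000, seed = NULL) {
  ks <- c(k_theta, k_gamma, k_gamma_dot, k_tau)
  stopifnot(
    is.numeric(ks), all(is.finite(ks)), all(ks >= 0),
    is.numeric(n_sims), length(n_sims) == 1, n_sims >= 1
  )
  structure(
    list(
      k_theta = k_theta, k_gamma = k_gamma, k_gamma_dot = k_gamma_dot,
      k_tau = k_tau, n_sims = as.integer(n_sims), seed = seed
    ),
    class = "weber_config"
  )
}

#' @export
print.ball_spec <- function(x, ...) {
  cat(sprintf(
    "<ball_spec> radius %.4g m (diameter %.4g m), Cd %.3g, mass %.3g kg\n",
    x$radius, x$size, x$drag_coefficient, x$mass
  ))
  invisible(x)
}

#' @export
print.env_spec <- function(x, ...) {
  cat(sprintf(
    "<env_spec> g %.4g m/s^2, air density %.4g kg/m^3, drag %s\n",
    x$gravity, x$air_density, if (x$drag_enabled) "on" else "off"
  ))
  invisible(x)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec> gravity %.4g m/s^2, size %.4g m\n", x$gravity, x$size
  ))
  invisible(x)
}
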