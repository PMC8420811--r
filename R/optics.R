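new_optical_stream <- function(tbl, flight_time, dt, radius) {
  out <- tibble::new_tibble(tbl, class = "optical_stream")
  attr(out, "flight_time") <- flight_time
  attr(out, "dt") <- dt
  attr(out, "radius") <- radius
  out
}

#' Project a trajectory into egocentric optical variables
#'
#' Computes, per time sample and relative to the observer's eye, the
#' quantities an observer can in principle extract from the optic flow:
#'
#' * `distance` — eye-to-ball distance D (m);
#' * `theta` — retinal size, the angular subtense of the ball,
#'   `2 * atan(radius / D)` (rad);
#' * `theta_dot` — rate of expansion (rad/s), positive while approaching;
#' * `gamma` — elevation angle above the eye-level horizontal plane,
#'   measured spherically through the current eye position (rad);
#' * `gamma_dot` — rate of change of the elevation angle (rad/s);
#' * `radial_speed` — `-dD/dt` (m/s), positive while approaching.
#'
#' Derivatives are computed analytically from the relative velocity (chain
#' rule), not by differencing the sampled series, so their accuracy does not
#' depend on `dt`. Samples where the eye is inside the ball (`D <= radius`,
#' e.g. the landing row of a head-on flight) have no defined optics and are
#' returned as `NA`.
#'
#' @param trajectory A `ttc_trajectory`.
#' @param ball A [ball_spec()]; only the radius enters the projection.
#' @param observer An `observer_path` on the same time grid, or `NULL` for a
#'   stationary eye at the origin.
#' @return An `optical_stream` tibble with columns
#'   `t, distance, theta, theta_dot, gamma, gamma_dot, radial_speed`.
#' @export
#' @examples
#' traj <- simulate_vacuum(make_head_on(30, 2))
#' stream <- project_optics(traj, baseball())
#' head(stream, 3)
project_optics <- function(trajectory, ball, observer = NULL) {
  stopifnot(inherits(ball, "ball_spec"))
  if (is.null(observer)) observer <- observer_stationary(trajectory)
  if (nrow(observer) != nrow(trajectory) ||
      max(abs(observer$t - trajectory$t)) > 1e-9) {
    abort("`observer` must share the trajectory's time grid.")
  }
  px <- trajectory$x - observer$x
  py <- trajectory$y - observer$y
  pz <- trajectory$z - observer$z
  vx <- trajectory$vx - observer$vx
  vy <- trajectory$vy - observer$vy
  vz <- trajectory$vz - observer$vz

  d <- sqrt(px^2 + py^2 + pz^2)
  if (all(d <= ball$radius)) {
    abort("Ball at the eye for every sample; optics undefined.")
  }
  h <- sqrt(px^2 + pz^2)
  ok <- d > ball$radius & h > 0

  d_dot <- (px * vx + py * vy + pz * vz) / d
  theta <- 2 * atan(ball$radius / d)
  theta_dot <- -2 * ball$radius * d_dot / (d^2 + ball$radius^2)
  gamma <- atan2(py, h)
  h_dot <- (px * vx + pz * vz) / h
  gamma_dot <- (vy * h - py * h_dot) / (h^2 + py^2)

  mask <- function(x) ifelse(ok, x, NA_real_)
  tbl <- tibble::tibble(
    t = trajectory$t,
    distance = mask(d),
    theta = mask(theta),
    theta_dot = mask(theta_dot),
    gamma = mask(gamma),
    gamma_dot = mask(gamma_dot),
    radial_speed = mask(-d_dot)
  )
  new_optical_stream(tbl, flight_time = attr(trajectory, "flight_time"),
                     dt = attr(trajectory, "dt"), radius = ball$radius)
}

#' Tau, the first-order TTC correlate
#'
#' `tau(t) = theta / theta_dot` wherever the image is expanding
#' (`theta_dot > 0`). While the ball recedes the expansion rate is negative
#' and Tau carries no usable TTC signal; those samples are returned as `NA`.
#'
#' @param stream An `optical_stream`.
#' @return A tibble with columns `t` and `tau` (seconds; `NA` when
#'   undefined).
#' @export
tau <- function(stream) {
  expanding <- !is.na(stream$theta_dot) & stream$theta_dot > 0
  tibble::tibble(
    t = stream$t,
    tau = ifelse(expanding, stream$theta / stream$theta_dot, NA_real_)
  )
}

#' Discriminability of the rate of expansion
#'
#' Flags the samples whose rate of expansion falls below the discrimination
#' threshold (default 0.004 rad/s, below which observers cannot tell
#' expansion rates apart). Receding samples (negative or undefined
#' `theta_dot`) count as below threshold. The fraction of the flight spent
#' below threshold is attached as the `fraction_below` attribute.
#'
#' @param stream An `optical_stream`.
#' @param threshold Discrimination threshold in rad/s (> 0 unless exactly 0,
#'   which isolates the receding phase).
#' @return A tibble `t, theta_dot, below` with attribute `fraction_below`.
#' @export
expansion_discriminable <- function(stream, threshold = 0.004) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  below <- is.na(stream$theta_dot) | stream$theta_dot < threshold
  out <- tibble::tibble(t = stream$t, theta_dot = stream$theta_dot,
                        below = below)
  attr(out, "fraction_below") <- mean(below)
  out
}

#' @rdname expansion_discriminable
#' @export
fraction_below_threshold <- function(stream, threshold = 0.004) {
  attr(expansion_discriminable(stream, threshold), "fraction_below")
}
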