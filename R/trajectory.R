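# Coordinate frame (fixed throughout the package): x lateral, y vertical up,
# z depth, with launches at eye level y = 0. Head-on scenarios place the
# observer's eye at the origin and the launch point on the +z axis.

new_trajectory <- function(tbl, flight_time, dt, launch_height = 0) {
  out <- tibble::new_tibble(tbl, class = "ttc_trajectory")
  attr(out, "flight_time") <- flight_time
  attr(out, "dt") <- dt
  attr(out, "launch_height") <- launch_height
  out
}

#' Flight time of a simulated trajectory or derived series
#'
#' @param x A `ttc_trajectory`, `optical_stream` or `ttc_series`.
#' @return Ground-truth flight time T in seconds.
#' @export
flight_time <- function(x) {
  ft <- attr(x, "flight_time")
  if (is.null(ft)) abort("`x` carries no flight_time attribute.")
  ft
}

#' Launch state
#'
#' Position and velocity of the ball at release, in the package frame
#' (x lateral, y vertical up, z depth; metres and m/s).
#'
#' @param position,velocity Numeric 3-vectors, finite.
#' @return A `launch_state` list.
#' @export
launch_state <- function(position, velocity) {
  stopifnot(
    is.numeric(position), length(position) == 3, all(is.finite(position)),
    is.numeric(velocity), length(velocity) == 3, all(is.finite(velocity))
  )
  structure(
    list(position = as.numeric(position), velocity = as.numeric(velocity)),
    class = "launch_state"
  )
}

#' Head-on launch toward the observer
#'
#' Builds the launch state of an eye-level parabola that, in vacuum, lands
#' exactly at the observer (the origin) after `flight_time` seconds:
#' vertical speed `g * T / 2` and horizontal speed `z_init / T` directed at
#' the origin.
#'
#' @param z_init Initial distance in depth, metres (> 0).
#' @param flight_time Intended vacuum flight time T in seconds (> 0).
#' @param env An [env_spec()] supplying gravity.
#' @return A [launch_state()] at `(0, 0, z_init)`.
#' @export
#' @examples
#' make_head_on(30, 2)
make_head_on <- function(z_init, flight_time, env = env_spec()) {
  stopifnot(
    is.numeric(z_init), length(z_init) == 1, is.finite(z_init), z_init > 0,
    is.numeric(flight_time), length(flight_time) == 1,
    is.finite(flight_time), flight_time > 0
  )
  launch_state(
    position = c(0, 0, z_init),
    velocity = c(0, env$gravity * flight_time / 2, -z_init / flight_time)
  )
}

#' Eye-level launch landing at an arbitrary point
#'
#' Like [make_head_on()] but aiming the vacuum parabola at an arbitrary
#' eye-level endpoint rather than the origin. Used for the interception-grid
#' scenarios where the ball lands ahead of, behind, or beside the observer.
#'
#' @param z_init Initial depth of the launch point, metres (> 0).
#' @param endpoint Numeric length-2 `(x_end, z_end)` or length-3
#'   `(x_end, 0, z_end)` landing point at eye level.
#' @inheritParams make_head_on
#' @return A [launch_state()].
#' @export
make_launch_to_point <- function(z_init, endpoint, flight_time,
                                 env = env_spec()) {
  stopifnot(z_init > 0, flight_time > 0, is.numeric(endpoint))
  if (length(endpoint) == 2) endpoint <- c(endpoint[1], 0, endpoint[2])
  stopifnot(length(endpoint) == 3)
  if (abs(endpoint[2]) > 1e-12) {
    abort("`endpoint` must lie at eye level (y = 0).")
  }
  start <- c(0, 0, z_init)
  launch_state(
    position = start,
    velocity = (endpoint - start) / flight_time +
      c(0, env$gravity * flight_time / 2, 0)
  )
}

#' Simulate a vacuum (gravity-only) trajectory
#'
#' Samples the exact analytic parabola on a uniform `dt` grid. The flight
#' terminates when the ball returns to its launch height (`T = 2 * v_y0 / g`
#' for an eye-level launch); the landing sample is always included as the
#' final row.
#'
#' @param launch A [launch_state()] with positive initial vertical speed.
#' @param env An [env_spec()].
#' @param dt Sampling step in seconds (> 0). Default 0.01.
#' @return A `ttc_trajectory` tibble with columns `t, x, y, z, vx, vy, vz`
#'   and attributes `flight_time` and `dt`.
#' @export
#' @examples
#' traj <- simulate_vacuum(make_head_on(30, 2))
#' flight_time(traj)
simulate_vacuum <- function(launch, env = env_spec(), dt = 0.01) {
  stopifnot(inherits(launch, "launch_state"), dt > 0)
  g <- env$gravity
  vy0 <- launch$velocity[2]
  if (vy0 <= 0) {
    abort("Degenerate launch: non-positive vertical speed gives T <= 0.")
  }
  tt <- 2 * vy0 / g
  times <- seq(0, tt, by = dt)
  if (tt - times[length(times)] > 1e-9) times <- c(times, tt)
  p0 <- launch$position
  v0 <- launch$velocity
  tbl <- tibble::tibble(
    t = times,
    x = p0[1] + v0[1] * times,
    y = p0[2] + vy0 * times - g / 2 * times^2,
    z = p0[3] + v0[3] * times,
    vx = rep(v0[1], length(times)),
    vy = vy0 - g * times,
    vz = rep(v0[3], length(times))
  )
  new_trajectory(tbl, flight_time = tt, dt = dt, launch_height = p0[2])
}

#' Simulate a trajectory under gravity and quadratic air drag
#'
#' Integrates `dv/dt = -g yhat - (rho * Cd * A / (2 m)) * |v| * v` with a
#' fixed-step classical 4th-order Runge-Kutta scheme on the `dt` grid.
#' Integration stops at the first downward crossing of the launch height;
#' the crossing time and state are located inside the bracketing step on
#' the cubic Hermite interpolant of the sampled state (so the landing time
#' inherits the integrator's accuracy) and appended as the final row.
#'
#' With `drag_coefficient = 0` the scheme reproduces the vacuum parabola to
#' machine precision (the gravity-only field is polynomial in time).
#'
#' @param launch A [launch_state()].
#' @param ball A [ball_spec()] supplying Cd, cross-section and mass.
#' @param env An [env_spec()] supplying gravity and air density.
#' @param dt Integration step in seconds (> 0). Default 0.01.
#' @return A `ttc_trajectory` tibble; see [simulate_vacuum()].
#' @export
#' @examples
#' traj <- simulate_drag(
#'   launch_state(c(0, 0, 0), c(0, 9.807, -25)),
#'   soccer_ball(), env_spec(drag_enabled = TRUE)
#' )
#' flight_time(traj) # < 2 s: drag shortens the flight
simulate_drag <- function(launch, ball, env = env_spec(drag_enabled = TRUE),
                          dt = 0.01) {
  stopifnot(inherits(launch, "launch_state"), inherits(ball, "ball_spec"),
            dt > 0)
  g <- env$gravity
  kd <- env$air_density * ball$drag_coefficient * ball$cross_section /
    (2 * ball$mass)
  if (launch$velocity[2] <= 0) {
    abort("Degenerate launch: non-positive vertical speed gives T <= 0.")
  }
  accel <- function(v) c(0, -g, 0) - kd * sqrt(sum(v^2)) * v

  y0 <- launch$position[2]
  max_steps <- 1e6
  pos <- launch$position
  vel <- launch$velocity
  ts <- numeric(max_steps)
  P <- matrix(NA_real_, max_steps, 3)
  V <- matrix(NA_real_, max_steps, 3)
  ts[1] <- 0
  P[1, ] <- pos
  V[1, ] <- vel
  n <- 1
  repeat {
    k1v <- accel(vel)
    k1p <- vel
    k2v <- accel(vel + dt / 2 * k1v)
    k2p <- vel + dt / 2 * k1v
    k3v <- accel(vel + dt / 2 * k2v)
    k3p <- vel + dt / 2 * k2v
    k4v <- accel(vel + dt * k3v)
    k4p <- vel + dt * k3v
    npos <- pos + dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p)
    nvel <- vel + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (!all(is.finite(npos)) || !all(is.finite(nvel))) {
      abort("Non-finite state during drag integration.")
    }
    tn <- ts[n] + dt
    if (npos[2] < y0 && pos[2] >= y0 && n > 1) {
      f <- crossing_fraction(pos[2] - y0, vel[2], npos[2] - y0, nvel[2], dt)
      tl <- ts[n] + f * dt
      pl <- hermite_point(pos, vel, npos, nvel, dt, f)
      vl <- vel + f * (nvel - vel)
      if (tl - ts[n] > 1e-9) {
        n <- n + 1
        ts[n] <- tl
        P[n, ] <- pl
        V[n, ] <- vl
      } else {
        ts[n] <- tl
        P[n, ] <- pl
        V[n, ] <- vl
      }
      break
    }
    n <- n + 1
    if (n > max_steps) abort("Drag integration exceeded the step budget.")
    ts[n] <- tn
    P[n, ] <- npos
    V[n, ] <- nvel
    pos <- npos
    vel <- nvel
  }
  tbl <- tibble::tibble(
    t = ts[1:n],
    x = P[1:n, 1], y = P[1:n, 2], z = P[1:n, 3],
    vx = V[1:n, 1], vy = V[1:n, 2], vz = V[1:n, 3]
  )
  new_trajectory(tbl, flight_time = ts[n], dt = dt, launch_height = y0)
}

# Locate the eye-level crossing inside the bracketing integration step on
# the cubic Hermite interpolant of the height (positions and velocities at
# both ends), so the landing time inherits the integrator's accuracy
# instead of the O(dt^2) error of a secant. Returns the step fraction.
crossing_fraction <- function(y_a, vy_a, y_b, vy_b, dt) {
  hermite <- function(s) {
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    h00 * y_a + h10 * dt * vy_a + h01 * y_b + h11 * dt * vy_b
  }
  stats::uniroot(hermite, c(0, 1), tol = 1e-14)$root
}

hermite_point <- function(p_a, v_a, p_b, v_b, dt, s) {
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * p_a + h10 * dt * v_a + h01 * p_b + h11 * dt * v_b
}

new_observer_path <- function(tbl, speed, start_delay, interception = NULL) {
  out <- tibble::new_tibble(tbl, class = "observer_path")
  attr(out, "speed") <- speed
  attr(out, "start_delay") <- start_delay
  attr(out, "interception") <- interception
  out
}

#' Stationary observer
#'
#' An observer whose eye stays at `position` on the trajectory's time grid.
#'
#' @param trajectory The paired `ttc_trajectory` (supplies the grid).
#' @param position Numeric 3-vector eye position, default the origin.
#' @return An `observer_path` tibble with columns `t, x, y, z, vx, vy, vz`.
#' @export
observer_stationary <- function(trajectory, position = c(0, 0, 0)) {
  stopifnot(is.numeric(position), length(position) == 3,
            all(is.finite(position)))
  n <- nrow(trajectory)
  tbl <- tibble::tibble(
    t = trajectory$t,
    x = rep(position[1], n), y = rep(position[2], n),
    z = rep(position[3], n),
    vx = rep(0, n), vy = rep(0, n), vz = rep(0, n)
  )
  new_observer_path(tbl, speed = 0, start_delay = 0, interception = position)
}

#' Observer running to the interception point
#'
#' The observer stays at `start` until `start_delay`, then moves along the
#' straight line to `interception_point` at the constant speed that makes it
#' arrive exactly at the trajectory's flight time
#' (`speed = |interception - start| / (T - start_delay)`).
#'
#' @param trajectory The paired `ttc_trajectory` (supplies grid and T).
#' @param interception_point Numeric 3-vector target of the run.
#' @param start Numeric 3-vector starting eye position, default the origin.
#' @param start_delay Seconds of stillness after launch (must be < T).
#'   Default 0.5 s, the usual latency before catchers start running.
#' @return An `observer_path` tibble; the attained speed is stored in the
#'   `speed` attribute.
#' @export
observer_path <- function(trajectory, interception_point,
                          start = c(0, 0, 0), start_delay = 0.5) {
  tt <- flight_time(trajectory)
  stopifnot(
    is.numeric(interception_point), length(interception_point) == 3,
    is.numeric(start), length(start) == 3,
    is.numeric(start_delay), length(start_delay) == 1, start_delay >= 0
  )
  if (start_delay >= tt) {
    abort("`start_delay` must be smaller than the flight time.")
  }
  disp <- interception_point - start
  dist <- sqrt(sum(disp^2))
  speed <- dist / (tt - start_delay)
  dir <- if (dist > 0) disp / dist else c(0, 0, 0)
  times <- trajectory$t
  # travelled distance, clamped between standstill and arrival
  s <- pmin(pmax(times - start_delay, 0), tt - start_delay) * speed
  moving <- times >= start_delay & times <= tt & dist > 0
  tbl <- tibble::tibble(
    t = times,
    x = start[1] + dir[1] * s,
    y = start[2] + dir[2] * s,
    z = start[3] + dir[3] * s,
    vx = ifelse(moving, dir[1] * speed, 0),
    vy = ifelse(moving, dir[2] * speed, 0),
    vz = ifelse(moving, dir[3] * speed, 0)
  )
  new_observer_path(tbl, speed = speed, start_delay = start_delay,
                    interception = interception_point)
}
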