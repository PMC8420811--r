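# Canonical study scenarios. Each scenario is a self-contained description
# (ball, environment, launch, observer behaviour, priors) that
# run_scenario() resolves into a (trajectory, observer, optics, TTC series)
# bundle.

new_scenario <- function(name, ball, env, launch, observer, drag = FALSE,
                         dt = 0.01, priors = prior_spec(), info = list()) {
  structure(
    list(name = name, ball = ball, env = env, launch = launch,
         observer = observer, drag = drag, dt = dt, priors = priors,
         info = info),
    class = "ttc_scenario"
  )
}

#' @export
print.ttc_scenario <- function(x, ...) {
  cat(sprintf("<ttc_scenario> %s (%s, observer: %s)\n", x$name,
              if (x$drag) "gravity + drag" else "vacuum",
              x$observer$type))
  invisible(x)
}

#' Head-on collision-course scenario family
#'
#' Eye-level vacuum parabolas on a collision course with a stationary
#' observer at the origin: one scenario per launch distance, all with the
#' same flight time. Defaults reproduce the accuracy/precision study
#' conditions (a baseball launched from 15, 20, 30, 40 and 50 m with a 2 s
#' flight, sampled at 0.01 s).
#'
#' @param z_init Vector of launch distances in metres.
#' @param flight_time Flight time in seconds.
#' @param ball A [ball_spec()].
#' @param gravity Gravitational acceleration in m/s^2.
#' @param dt Sampling step in seconds.
#' @return A named list of `ttc_scenario` objects.
#' @export
scenarios_head_on <- function(z_init = c(15, 20, 30, 40, 50),
                              flight_time = 2, ball = baseball(),
                              gravity = 9.807, dt = 0.01) {
  env <- env_spec(gravity = gravity)
  out <- lapply(z_init, function(z) {
    new_scenario(
      name = sprintf("head_on_z%g", z),
      ball = ball, env = env,
      launch = make_head_on(z, flight_time, env),
      observer = list(type = "stationary", position = c(0, 0, 0)),
      dt = dt,
      priors = prior_spec(gravity = gravity, size = ball$size)
    )
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Interception-point grid around the observer
#'
#' Vacuum parabolas launched from one distance toward eight eye-level
#' endpoints on the 3 x 3 grid `{-5, 0, 5} x {-5, 0, 5}` metres around the
#' observer (in lateral x and depth z), excluding the origin. Negative
#' `z_end` means the ball overflies the observer and lands behind them.
#' With `moving = TRUE` the observer runs from the origin to the
#' interception point, starting `start_delay` seconds after launch and
#' arriving exactly at landing.
#'
#' @param z_init Launch distance, default 50 m.
#' @param flight_time Flight time, default 2 s.
#' @param offsets Endpoint offsets along each axis, default `c(-5, 0, 5)`.
#' @param moving Should the observer run to the interception point?
#' @param start_delay Stillness before the run starts, default 0.5 s.
#' @param ball A [ball_spec()].
#' @param gravity Gravitational acceleration.
#' @param dt Sampling step.
#' @return A named list of `ttc_scenario` objects (8 for the defaults).
#' @export
scenarios_endpoint_grid <- function(z_init = 50, flight_time = 2,
                                    offsets = c(-5, 0, 5), moving = FALSE,
                                    start_delay = 0.5, ball = baseball(),
                                    gravity = 9.807, dt = 0.01) {
  env <- env_spec(gravity = gravity)
  grid <- tidyr::expand_grid(x_end = offsets, z_end = offsets)
  grid <- grid[!(grid$x_end == 0 & grid$z_end == 0), ]
  out <- purrr::pmap(grid, function(x_end, z_end) {
    endpoint <- c(x_end, 0, z_end)
    observer <- if (moving) {
      list(type = "path", start = c(0, 0, 0), interception = endpoint,
           start_delay = start_delay)
    } else {
      list(type = "stationary", position = c(0, 0, 0))
    }
    new_scenario(
      name = sprintf("end_x%+g_z%+g%s", x_end, z_end,
                     if (moving) "_moving" else ""),
      ball = ball, env = env,
      launch = make_launch_to_point(z_init, endpoint, flight_time, env),
      observer = observer, dt = dt,
      priors = prior_spec(gravity = gravity, size = ball$size),
      info = list(endpoint = endpoint)
    )
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Worst-case air-drag scenario
#'
#' The drag condition that stresses the GS estimator hardest: a soccer ball
#' launched with vertical speed 9.807 m/s (2 s of vacuum flight) and the
#' highest horizontal approach speed, 25 m/s, under sea-level air drag. The
#' launch point is placed so the drag trajectory lands at the origin.
#' Three observer placements are available:
#'
#' * `"interception"` — stationary at the drag landing point;
#' * `"midpoint_stationary"` — stationary halfway between the vacuum and
#'   drag landing points;
#' * `"midpoint_moving"` — starts at that midpoint and runs to the drag
#'   landing point at constant speed from `start_delay` after launch.
#'
#' The vacuum/drag landing points, both flight times and the implied
#' observer speed are recorded in `$info`.
#'
#' @param observer Observer placement, see above.
#' @param ball A [ball_spec()], default [soccer_ball()].
#' @param v_y0 Launch vertical speed, m/s.
#' @param v_z0 Horizontal approach speed, m/s.
#' @param gravity,air_density Environment parameters.
#' @param start_delay Stillness before the run starts (moving case).
#' @param dt Integration step.
#' @return A `ttc_scenario` with populated `$info`.
#' @export
#' @examples
#' sc <- scenario_drag_worst_case("midpoint_moving")
#' sc$info$observer_speed # ~8.1 m/s
scenario_drag_worst_case <- function(observer = c("interception",
                                                  "midpoint_stationary",
                                                  "midpoint_moving"),
                                     ball = soccer_ball(), v_y0 = 9.807,
                                     v_z0 = 25, gravity = 9.807,
                                     air_density = 1.225, start_delay = 0.5,
                                     dt = 0.01) {
  observer <- match.arg(observer)
  env <- env_spec(gravity = gravity, air_density = air_density,
                  drag_enabled = TRUE)
  probe <- launch_state(c(0, 0, 0), c(0, v_y0, -v_z0))
  drag_traj <- simulate_drag(probe, ball, env, dt = dt)
  vac_traj <- simulate_vacuum(probe, env, dt = dt)
  range_drag <- -drag_traj$z[nrow(drag_traj)]
  range_vac <- -vac_traj$z[nrow(vac_traj)]
  t_drag <- flight_time(drag_traj)
  # launch placed so the drag trajectory lands at the origin; the vacuum
  # landing point then sits beyond the origin (negative z)
  launch <- launch_state(c(0, 0, range_drag), c(0, v_y0, -v_z0))
  midpoint <- c(0, 0, (range_drag - range_vac) / 2)
  obs <- switch(observer,
    interception = list(type = "stationary", position = c(0, 0, 0)),
    midpoint_stationary = list(type = "stationary", position = midpoint),
    midpoint_moving = list(type = "path", start = midpoint,
                           interception = c(0, 0, 0),
                           start_delay = start_delay)
  )
  speed <- sqrt(sum(midpoint^2)) / (t_drag - start_delay)
  new_scenario(
    name = paste0("drag_worst_", observer),
    ball = ball, env = env, launch = launch, observer = obs,
    drag = TRUE, dt = dt,
    priors = prior_spec(gravity = gravity, size = ball$size),
    info = list(
      flight_time_drag = t_drag,
      flight_time_vacuum = flight_time(vac_traj),
      range_drag = range_drag,
      range_vacuum = range_vac,
      midpoint = midpoint,
      observer_speed = if (observer == "midpoint_moving") speed else NA_real_
    )
  )
}

#' Run a scenario end to end
#'
#' Resolves a scenario into its trajectory (vacuum or drag), observer path,
#' optical stream and GS prediction series.
#'
#' @param scenario A `ttc_scenario`.
#' @param window Slope window passed to [ttc_gs_series()].
#' @return A `scenario_run` list with elements `scenario`, `trajectory`,
#'   `observer`, `stream` and `ttc`.
#' @export
#' @examples
#' run <- run_scenario(scenarios_head_on(30)[[1]])
#' max(abs(run$ttc$error), na.rm = TRUE)
run_scenario <- function(scenario, window = 0.2) {
  stopifnot(inherits(scenario, "ttc_scenario"))
  traj <- if (scenario$drag) {
    simulate_drag(scenario$launch, scenario$ball, scenario$env,
                  dt = scenario$dt)
  } else {
    simulate_vacuum(scenario$launch, scenario$env, dt = scenario$dt)
  }
  obs <- scenario$observer
  observer <- switch(obs$type,
    stationary = observer_stationary(traj, obs$position),
    path = observer_path(traj, obs$interception, start = obs$start,
                         start_delay = obs$start_delay),
    abort(sprintf("Unknown observer type '%s'.", obs$type))
  )
  stream <- project_optics(traj, scenario$ball, observer)
  series <- ttc_gs_series(stream, scenario$priors, window = window)
  structure(
    list(scenario = scenario, trajectory = traj, observer = observer,
         stream = stream, ttc = series),
    class = "scenario_run"
  )
}

#' Interpolate the TTC error at a given time
#'
#' Linear interpolation of the signed prediction error of a `ttc_series`
#' (or `scenario_run`) at arbitrary probe times, e.g. "one second before
#' contact".
#'
#' @param x A `ttc_series` or `scenario_run`.
#' @param at Probe time(s) in seconds.
#' @return Interpolated error(s) in seconds.
#' @export
error_at <- function(x, at) {
  series <- if (inherits(x, "scenario_run")) x$ttc else x
  ok <- is.finite(series$error)
  approx(series$t[ok], series$error[ok], xout = at)$y
}
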