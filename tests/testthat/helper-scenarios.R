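# Shared fixtures, built in code.

# Optical stream of a head-on eye-level vacuum flight toward an observer at
# the origin.
head_on_stream <- function(z_init, flight_time = 2, ball = baseball(),
                           gravity = 9.807, dt = 0.01) {
  env <- env_spec(gravity = gravity)
  traj <- simulate_vacuum(make_head_on(z_init, flight_time, env), env, dt)
  project_optics(traj, ball)
}

# A constant-velocity level approach toward the eye (not a parabola), built
# directly on the trajectory container for Tau's small-angle oracle.
constant_approach <- function(d0 = 10, speed = 5, t_end = 1, dt = 0.01) {
  times <- seq(0, t_end, by = dt)
  tbl <- tibble::tibble(
    t = times,
    x = 0, y = 0, z = d0 - speed * times,
    vx = 0, vy = 0, vz = -speed
  )
  ttcgs:::new_trajectory(tbl, flight_time = d0 / speed, dt = dt)
}

# Steep short launch (2 m away, 10 m apex): the ball recedes from the eye
# during the early flight.
receding_stream <- function(ball = baseball()) {
  g <- 9.807
  vy0 <- sqrt(2 * g * 10)
  tt <- 2 * vy0 / g
  traj <- simulate_vacuum(launch_state(c(0, 0, 2), c(0, vy0, -2 / tt)))
  project_optics(traj, ball)
}

# Three-sigma binomial band around an accuracy estimate.
binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
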