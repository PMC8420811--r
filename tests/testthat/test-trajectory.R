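test_that("head-on launches satisfy the closed-form construction", {
  launch <- make_head_on(30, 2, env_spec(gravity = 9.807))
  expect_equal(launch$position, c(0, 0, 30))
  expect_equal(launch$velocity[2], 9.807 * 2 / 2)
  expect_equal(launch$velocity[3], -15)

  traj <- simulate_vacuum(launch)
  land <- traj[nrow(traj), ]
  expect_lt(sqrt(land$x^2 + land$y^2 + land$z^2), 1e-9)

  # apex of the 15 m launch: y = v_y0 * t - g t^2 / 2 peaks at T/2
  traj15 <- simulate_vacuum(make_head_on(15, 2))
  apex <- traj15[traj15$t == 1, ]
  expect_equal(apex$y, 4.9035, tolerance = 1e-12)
  expect_equal(apex$vy, 0, tolerance = 1e-12)

  expect_error(make_head_on(-5, 2))
  expect_error(make_head_on(30, 0))
})

test_that("vacuum flight time follows 2 * v_y0 / g", {
  traj <- simulate_vacuum(launch_state(c(0, 0, 30), c(0, 9.807, -15)))
  expect_identical(flight_time(traj), 2)

  # doubling gravity halves the flight for the same vertical speed
  t2 <- simulate_vacuum(launch_state(c(0, 0, 30), c(0, 9.807, -15)),
                        env_spec(gravity = 2 * 9.807))
  expect_equal(flight_time(t2), 1)

  # horizontal range equals v_z * T for an eye-level launch and landing
  expect_equal(traj$z[nrow(traj)] - traj$z[1], -15 * 2, tolerance = 1e-12)

  expect_error(simulate_vacuum(launch_state(c(0, 0, 1), c(0, 0, -1))),
               "Degenerate")
})

test_that("vacuum samples conserve energy and match the parabola exactly", {
  launch <- launch_state(c(1, 0, 40), c(2, 8, -12))
  g <- 9.807
  traj <- simulate_vacuum(launch, env_spec(gravity = g), dt = 0.01)
  energy <- (traj$vx^2 + traj$vy^2 + traj$vz^2) / 2 + g * traj$y
  expect_lt(diff(range(energy)) / energy[1], 1e-9)
  y_exact <- 8 * traj$t - g / 2 * traj$t^2
  expect_lt(max(abs(traj$y - y_exact)), 1e-9)
})

test_that("the drag integrator degenerates to the vacuum parabola at Cd = 0", {
  launch <- launch_state(c(0, 0, 30), c(0, 9.807, -15))
  ball0 <- ball_spec(radius = 0.037, drag_coefficient = 0, mass = 0.145)
  vac <- simulate_vacuum(launch)
  drg <- simulate_drag(launch, ball0)
  expect_equal(nrow(drg), nrow(vac))
  expect_lt(max(abs(drg$y - vac$y)), 1e-6)
  expect_lt(max(abs(drg$z - vac$z)), 1e-6)
  expect_equal(flight_time(drg), flight_time(vac), tolerance = 1e-9)
})

test_that("drag shortens flight and range, monotonically in Cd and area", {
  launch <- launch_state(c(0, 0, 0), c(0, 9.807, -25))
  vac <- simulate_vacuum(launch)
  range_of <- function(tr) abs(tr$z[nrow(tr)] - tr$z[1])
  soc <- simulate_drag(launch, soccer_ball())
  expect_lt(flight_time(soc), flight_time(vac))
  expect_lt(range_of(soc), range_of(vac))
  # worst-case study figures: under 2 s and under 50 m
  expect_lt(flight_time(soc), 2)
  expect_lt(range_of(soc), 50)

  half_cd <- simulate_drag(launch, soccer_ball(drag_coefficient = 0.2))
  expect_gt(flight_time(half_cd), flight_time(soc))
  expect_gt(range_of(half_cd), range_of(soc))

  small <- simulate_drag(launch, soccer_ball(radius = 0.05))
  expect_gt(flight_time(small), flight_time(soc))
  expect_gt(range_of(small), range_of(soc))
})

test_that("the drag integrator converges under step halving", {
  launch <- launch_state(c(0, 0, 0), c(0, 9.807, -25))
  t1 <- flight_time(simulate_drag(launch, soccer_ball(), dt = 0.01))
  t2 <- flight_time(simulate_drag(launch, soccer_ball(), dt = 0.005))
  expect_lt(abs(t1 - t2), 1e-6)
})

test_that("observer paths reach the interception point just in time", {
  traj <- simulate_vacuum(make_head_on(30, 2))
  path <- observer_path(traj, c(0, 0, 5), start = c(0, 0, 0),
                        start_delay = 0.5)
  expect_equal(attr(path, "speed"), 5 / 1.5)
  # stationary before the delay, at the target at landing
  expect_true(all(path$z[path$t < 0.5] == 0))
  final <- path[nrow(path), ]
  expect_lt(abs(final$z - 5), 1e-9)

  same <- observer_path(traj, c(0, 0, 0), start = c(0, 0, 0))
  expect_equal(attr(same, "speed"), 0)
  expect_true(all(same$z == 0) && all(same$vz == 0))

  expect_error(observer_path(traj, c(0, 0, 5), start_delay = 2.5),
               "start_delay")
})
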