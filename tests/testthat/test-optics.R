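test_that("projection matches the closed-form geometry at launch", {
  stream <- head_on_stream(30)
  expect_equal(stream$distance[1], 30)
  expect_equal(stream$theta[1], 2 * atan(0.037 / 30))
  expect_equal(stream$gamma[1], 0)
  # at gamma = 0 the elevation rate is the vertical speed over the distance
  expect_equal(stream$gamma_dot[1], 9.807 / 30, tolerance = 1e-12)
  expect_equal(stream$radial_speed[1], 15, tolerance = 1e-12)
})

test_that("analytic derivatives agree with finite differences", {
  central_diff <- function(x, dt) {
    n <- length(x)
    c(NA, (x[3:n] - x[1:(n - 2)]) / (2 * dt), NA)
  }
  check_stream <- function(stream, dt, tol_gd = 1e-6, tol_td = 1e-6) {
    gd_fd <- central_diff(stream$gamma, dt)
    td_fd <- central_diff(stream$theta, dt)
    # stay clear of the near-eye passage (third derivatives blow up there,
    # so finite-difference truncation dominates) and of the final samples,
    # where the appended landing row breaks the uniform spacing
    i <- which(is.finite(gd_fd) & is.finite(td_fd) &
                 is.finite(stream$gamma_dot) & is.finite(stream$theta_dot) &
                 stream$distance > 5)
    i <- i[i < nrow(stream) - 1]
    expect_gt(length(i), 100)
    expect_lt(max(abs(stream$gamma_dot[i] - gd_fd[i])), tol_gd)
    expect_lt(max(abs(stream$theta_dot[i] - td_fd[i])), tol_td)
  }
  check_stream(head_on_stream(30, dt = 0.001), 0.001)

  withr::with_seed(7, {
    for (k in 1:5) {
      launch <- launch_state(
        c(runif(1, -5, 5), 0, runif(1, 10, 40)),
        c(runif(1, -3, 3), runif(1, 5, 12), runif(1, -20, -5))
      )
      traj <- simulate_vacuum(launch, dt = 0.001)
      # lateral launches can pass nearly overhead, where the elevation rate
      # changes fast enough that fd truncation needs a looser budget
      check_stream(project_optics(traj, baseball()), 0.001, tol_gd = 2e-5)
    }
  })
})

test_that("retinal size shrinks with distance within the small-angle bound", {
  d <- seq(2, 60, by = 0.5)
  theta <- 2 * atan(0.037 / d)
  expect_true(all(diff(theta) < 0))
  d_hat <- distance_from_size(0.074, theta)
  rel_err <- (d_hat - d) / d
  expect_true(all(rel_err >= 0))
  expect_true(all(rel_err <= (0.037 / d)^2 / 3 * 1.001))
})

test_that("the elevation angle of a head-on flight rises monotonically", {
  for (z in c(15, 30, 50)) {
    gamma <- head_on_stream(z)$gamma
    gamma <- gamma[!is.na(gamma)]
    expect_true(all(diff(gamma) > 0))
  }
})

test_that("projection is translation-equivariant for moving observers", {
  traj <- simulate_vacuum(make_launch_to_point(50, c(5, 0, -5), 2))
  obs <- observer_path(traj, c(5, 0, -5), start_delay = 0.5)
  direct <- project_optics(traj, baseball(), obs)

  rel <- tibble::tibble(
    t = traj$t,
    x = traj$x - obs$x, y = traj$y - obs$y, z = traj$z - obs$z,
    vx = traj$vx - obs$vx, vy = traj$vy - obs$vy, vz = traj$vz - obs$vz
  )
  rel_traj <- ttcgs:::new_trajectory(rel, flight_time(traj),
                                     attr(traj, "dt"))
  relative <- project_optics(rel_traj, baseball())
  expect_equal(direct, relative, ignore_attr = TRUE)
})

test_that("tau approximates distance over speed for a constant approach", {
  stream <- project_optics(constant_approach(10, 5), baseball())
  tau_hat <- tau(stream)$tau
  tau_true <- (10 - 5 * stream$t) / 5
  keep <- stream$t <= 0.8 # stay clear of very close range
  expect_lt(max(abs(tau_hat[keep] - tau_true[keep]) / tau_true[keep]),
            0.001)
})

test_that("tau is undefined while the ball recedes or expansion stalls", {
  stream <- receding_stream()
  early <- stream$t > 0.1 & stream$t < 0.5
  expect_true(all(stream$theta_dot[early] < 0))
  expect_true(all(is.na(tau(stream)$tau[early])))
  # late flight approaches the eye again: tau comes back
  expect_true(any(!is.na(tau(stream)$tau)))
  # exactly stalled expansion is in-band missing
  flat <- tibble::tibble(t = 0, theta = 0.1, theta_dot = 0)
  expect_true(is.na(tau(flat)$tau))
})

test_that("expansion discriminability orders soccer below baseball", {
  for (z in c(15, 20, 30, 40, 50)) {
    fb <- fraction_below_threshold(head_on_stream(z, ball = baseball()))
    fs <- fraction_below_threshold(head_on_stream(z, ball = soccer_ball()))
    expect_lt(fs, fb)
  }
  # zero threshold isolates the receding phase
  expect_equal(fraction_below_threshold(head_on_stream(30), 0),
               1 / nrow(head_on_stream(30))) # only the landing NA row
  rec <- receding_stream()
  expect_equal(fraction_below_threshold(rec, 0),
               mean(is.na(rec$theta_dot) | rec$theta_dot < 0))
})
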