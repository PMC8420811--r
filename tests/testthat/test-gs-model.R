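test_that("size calibration recovers distance and approach speed", {
  expect_equal(distance_from_size(0.074, 0.0074), 10)
  theta30 <- 2 * atan(0.037 / 30)
  expect_lt(abs(distance_from_size(0.074, theta30) - 30) / 30, 1e-4)
  expect_error(distance_from_size(0.074, 0), "positive")

  # constant approach at 5 m/s seen from 10 m
  d <- 10
  theta <- 2 * atan(0.037 / d)
  theta_dot <- 2 * 0.037 * 5 / (d^2 + 0.037^2)
  v_hat <- approach_speed_from_size(0.074, theta, theta_dot)
  expect_lt(abs(v_hat - 5) / 5, 0.001)
  expect_equal(approach_speed_from_size(0.074, 0.01, 0), 0)
  expect_lt(approach_speed_from_size(0.074, 0.01, -0.001), 0)
})

test_that("the GS estimate is exact at launch and proportional to priors", {
  z <- 30
  theta <- 2 * atan(0.037 / z)
  gamma_dot <- 9.807 / z
  est <- ttc_gs(theta, 0, gamma_dot)
  expect_lt(abs(est - 2) / 2, 1e-4)

  expect_equal(ttc_gs(theta, 0.1, 0), 0)
  base <- ttc_gs(theta, 0.05, gamma_dot)
  expect_equal(ttc_gs(theta, 0.05, gamma_dot,
                      prior_spec(gravity = 2 * 9.807)), base / 2)
  expect_equal(ttc_gs(theta, 0.05, gamma_dot,
                      prior_spec(size = 2 * 0.074)), base * 2)
  expect_error(ttc_gs(-0.01, 0, 0.3), "positive")
})

test_that("collision-course predictions stay within 10 ms and slope -1", {
  worst <- 0
  for (z in c(15, 20, 30, 40, 50)) {
    series <- ttc_gs_series(head_on_stream(z))
    worst <- max(worst, max(abs(series$error), na.rm = TRUE))
    nav <- navigation_signal(series)
    sig <- nav$signal[!is.na(nav$signal)]
    expect_true(all(sig == "hold"))
    ok <- !is.na(series$slope)
    expect_true(all(abs(series$slope[ok] + 1) < 0.05))
  }
  expect_lt(worst, 0.010)
})

test_that("prior errors propagate proportionally at launch", {
  series_for <- function(priors) {
    ttc_gs_series(head_on_stream(30), priors)$predicted[1]
  }
  exact <- series_for(prior_spec())
  big_ball <- series_for(prior_spec(size = 0.074 * 1.05))
  low_g <- series_for(prior_spec(gravity = 9.807 * 0.95))
  expect_equal(big_ball / exact, 1.05, tolerance = 1e-9)
  expect_equal(low_g / exact, 1 / 0.95, tolerance = 1e-9)
})

test_that("off-target landings bias the prediction in opposite directions", {
  traj_to <- function(z_end) {
    simulate_vacuum(make_launch_to_point(50, c(0, 0, z_end), 2))
  }
  series_for <- function(z_end) {
    ttc_gs_series(project_optics(traj_to(z_end), baseball()))
  }
  over <- series_for(-5)  # lands 5 m beyond (behind) the observer
  under <- series_for(5)  # lands 5 m short (in front)
  mid <- over$t >= 1.2 & over$t <= 1.6
  expect_true(all(over$error[mid] > 0))
  expect_true(all(over$slope[mid] > -1))
  expect_true(all(under$error[mid] < 0))
  expect_true(all(under$slope[mid] < -1))
})

test_that("MLE fusion follows the inverse-variance rules", {
  same <- combine_mle(2, 0.05, 2, 0.05)
  expect_equal(same$estimate, 2)
  expect_equal(same$wf, 0.05 / sqrt(2))

  dominant <- combine_mle(2, 0.05, 3, 1e6)
  expect_equal(dominant$estimate, 2, tolerance = 1e-9)
  expect_equal(dominant$wf, 0.05, tolerance = 1e-9)

  one_na <- combine_mle(NA_real_, NA_real_, 1.5, 0.1)
  expect_equal(one_na$estimate, 1.5)
  expect_equal(one_na$wf, 0.1)
  expect_true(is.na(combine_mle(NA_real_, 0.1, NA_real_, 0.1)$estimate))

  withr::with_seed(11, {
    for (k in 1:50) {
      ta <- runif(1, 0.5, 3)
      tb <- runif(1, 0.5, 3)
      wa <- runif(1, 0.01, 0.5)
      wb <- runif(1, 0.01, 0.5)
      fused <- combine_mle(ta, wa, tb, wb)
      sd_min <- min(wa * ta, wb * tb)
      expect_lte(fused$wf * fused$estimate, sd_min + 1e-12)
    }
  })
})

test_that("navigation slope windows are validated", {
  series <- ttc_gs_series(head_on_stream(30))
  expect_error(navigation_signal(series, window = 0.005), "two samples")
  expect_error(navigation_signal(series, window = 10), "longer")
})
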