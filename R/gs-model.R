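# The GS estimator used throughout this file:
#
#   TTC_GS = (2 / g) * (s / theta) * gamma_dot / cos(gamma)
#
# with s the assumed ball diameter and g the assumed gravity. s / theta is
# the known-size distance estimate; g normalizes the elevation-angle rate so
# the result is a time. For a head-on eye-level vacuum parabola this
# expression is algebraically exact up to the small-angle approximation
# s / theta ~ D (see the methods vignette for the derivation), which is what
# makes it a calibrated TTC signal rather than a mere correlate.

#' Distance from known size
#'
#' `d = s / theta`: the known physical diameter divided by the retinal size
#' gives a distance estimate, exact to first order in the angular size.
#'
#' @param size Assumed ball diameter in metres (> 0).
#' @param theta Retinal size in radians; all non-missing values must be
#'   positive. `NA` propagates.
#' @return Distance estimate(s) in metres.
#' @export
#' @examples
#' distance_from_size(0.074, 0.0074) # 10 m
distance_from_size <- function(size, theta) {
  stopifnot(is.numeric(size), all(size > 0))
  if (any(!is.na(theta) & theta <= 0)) {
    abort("`theta` must be positive (degenerate retinal size).")
  }
  size / theta
}

#' Approach speed from known size
#'
#' `V_z = s * theta_dot / theta^2`: known size calibrates retinal size and
#' its rate of expansion into an approach-speed estimate. A receding ball
#' (`theta_dot < 0`) yields a negative speed.
#'
#' @inheritParams distance_from_size
#' @param theta_dot Rate of expansion in rad/s.
#' @return Approach speed estimate(s) in m/s (positive toward the eye).
#' @export
approach_speed_from_size <- function(size, theta, theta_dot) {
  stopifnot(is.numeric(size), all(size > 0))
  if (any(!is.na(theta) & theta <= 0)) {
    abort("`theta` must be positive (degenerate retinal size).")
  }
  size * theta_dot / theta^2
}

#' GS time-to-contact estimate
#'
#' Evaluates `TTC_GS = (2 / g) * (s / theta) * gamma_dot / cos(gamma)` with
#' the gravity and size priors. All arguments are vectorized; `NA` optics
#' propagate to `NA` estimates.
#'
#' @param theta Retinal size (rad); non-missing values must be positive.
#' @param gamma Elevation angle (rad).
#' @param gamma_dot Rate of change of the elevation angle (rad/s).
#' @param priors A [prior_spec()] with the assumed gravity and diameter.
#' @return TTC estimate(s) in seconds.
#' @export
#' @examples
#' # launch instant of a 2 s head-on flight from 30 m
#' ttc_gs(2 * atan(0.037 / 30), 0, 9.807 / 30) # ~2 s
ttc_gs <- function(theta, gamma, gamma_dot, priors = prior_spec()) {
  stopifnot(inherits(priors, "prior_spec"))
  if (any(!is.na(theta) & theta <= 0)) {
    abort("`theta` must be positive (degenerate retinal size).")
  }
  (2 / priors$gravity) * (priors$size / theta) * gamma_dot / cos(gamma)
}

# Trailing-window ordinary-least-squares slope of x against t. Window is in
# the units of t and includes the current sample; NA samples are dropped.
rolling_slope <- function(t, x, window) {
  n <- length(t)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- which(t > t[i] - window - 1e-12 & t <= t[i] + 1e-12)
    idx <- idx[is.finite(x[idx])]
    if (length(idx) >= 2 && var(t[idx]) > 0) {
      out[i] <- cov(t[idx], x[idx]) / var(t[idx])
    }
  }
  out
}

new_ttc_series <- function(tbl, flight_time, window, priors) {
  out <- tibble::new_tibble(tbl, class = "ttc_series")
  attr(out, "flight_time") <- flight_time
  attr(out, "window") <- window
  attr(out, "priors") <- priors
  out
}

#' GS prediction series along a flight
#'
#' Applies [ttc_gs()] to every sample of an optical stream and pairs the
#' prediction with the ground truth: `true_remaining = T - t`, the signed
#' `error = predicted - true_remaining`, and the local slope of the
#' predicted TTC (trailing ordinary-least-squares line over `window`
#' seconds). An exact prediction decays at slope -1; departures from -1 are
#' the navigation signal read out by [navigation_signal()].
#'
#' @param stream An `optical_stream`.
#' @param priors A [prior_spec()].
#' @param flight_time Ground-truth flight time; defaults to the stream's
#'   attribute.
#' @param window Slope window in seconds, default 0.2 (20 samples at the
#'   default grid).
#' @return A `ttc_series` tibble with columns
#'   `t, predicted, true_remaining, error, slope`.
#' @export
#' @examples
#' traj <- simulate_vacuum(make_head_on(30, 2))
#' series <- ttc_gs_series(project_optics(traj, baseball()))
#' max(abs(series$error), na.rm = TRUE) # well under 10 ms
ttc_gs_series <- function(stream, priors = prior_spec(),
                          flight_time = NULL, window = 0.2) {
  if (nrow(stream) == 0) abort("`stream` is empty.")
  tt <- flight_time %||% attr(stream, "flight_time")
  if (is.null(tt)) abort("No flight time available for the stream.")
  predicted <- ttc_gs(stream$theta, stream$gamma, stream$gamma_dot, priors)
  tbl <- tibble::tibble(
    t = stream$t,
    predicted = predicted,
    true_remaining = tt - stream$t,
    error = predicted - (tt - stream$t),
    slope = rolling_slope(stream$t, predicted, window)
  )
  new_ttc_series(tbl, flight_time = tt, window = window, priors = priors)
}

#' Navigation signal from the TTC slope
#'
#' An exactly calibrated TTC prediction decreases at slope -1. A slope above
#' -1 (TTC shrinking too slowly) means the ball will land beyond the
#' observer, who should move away from the launch direction
#' (`move_backward`); a slope below -1 means it will land short
#' (`move_forward`); within `tolerance` of -1 the observer holds.
#'
#' @param series A `ttc_series`.
#' @param window Slope window in seconds; defaults to the window the series
#'   was built with. Must cover at least two samples.
#' @param tolerance Half-width of the hold band around -1, default 0.05.
#' @return A tibble `t, slope, signal` where `signal` is a factor with
#'   levels `move_forward`, `hold`, `move_backward` (`NA` where the slope is
#'   not yet defined).
#' @export
navigation_signal <- function(series, window = NULL, tolerance = 0.05) {
  window <- window %||% attr(series, "window") %||% 0.2
  dt_min <- min(diff(series$t))
  if (window < 2 * dt_min) {
    abort("`window` must span at least two samples.")
  }
  if (window > diff(range(series$t))) {
    abort("`window` is longer than the series.")
  }
  slope <- rolling_slope(series$t, series$predicted, window)
  signal <- dplyr::case_when(
    is.na(slope) ~ NA_character_,
    slope > -1 + tolerance ~ "move_backward",
    slope < -1 - tolerance ~ "move_forward",
    TRUE ~ "hold"
  )
  tibble::tibble(
    t = series$t,
    slope = slope,
    signal = factor(signal,
                    levels = c("move_forward", "hold", "move_backward"))
  )
}

#' Maximum-likelihood fusion of two TTC cues
#'
#' Inverse-variance weighting of two TTC estimates whose reliabilities are
#' expressed as Weber fractions: each cue's standard deviation is taken to
#' be `wf * estimate`, the fused estimate is the precision-weighted mean and
#' the fused variance is `1 / sum(1 / sigma_i^2)`. An undefined cue (`NA`
#' estimate or `NA` Weber fraction) is excluded, so the other cue passes
#' through unchanged; the fused Weber fraction never exceeds that of the
#' more reliable cue.
#'
#' @param ttc_a,ttc_b Cue estimates in seconds (vectorized).
#' @param wf_a,wf_b Their Weber fractions (> 0 where the cue is defined).
#' @return A tibble with columns `estimate` and `wf`.
#' @export
#' @examples
#' combine_mle(2, 0.05, 2, 0.05) # same estimate, wf / sqrt(2)
combine_mle <- function(ttc_a, wf_a, ttc_b, wf_b) {
  n <- max(length(ttc_a), length(ttc_b), length(wf_a), length(wf_b))
  ttc_a <- rep_len(ttc_a, n)
  ttc_b <- rep_len(ttc_b, n)
  wf_a <- rep_len(wf_a, n)
  wf_b <- rep_len(wf_b, n)
  ok_a <- is.finite(ttc_a) & is.finite(wf_a) & wf_a > 0
  ok_b <- is.finite(ttc_b) & is.finite(wf_b) & wf_b > 0
  va <- ifelse(ok_a, (wf_a * ttc_a)^2, Inf)
  vb <- ifelse(ok_b, (wf_b * ttc_b)^2, Inf)
  wa <- ifelse(va > 0, 1 / va, Inf)
  wb <- ifelse(vb > 0, 1 / vb, Inf)
  est <- ifelse(
    ok_a & ok_b, (wa * ttc_a + wb * ttc_b) / (wa + wb),
    ifelse(ok_a, ttc_a, ifelse(ok_b, ttc_b, NA_real_))
  )
  sigma <- ifelse(
    ok_a & ok_b, sqrt(1 / (wa + wb)),
    ifelse(ok_a, sqrt(va), ifelse(ok_b, sqrt(vb), NA_real_))
  )
  # a zero-variance cue (estimate exactly 0) dominates outright
  exact_a <- ok_a & va == 0
  exact_b <- ok_b & vb == 0 & !exact_a
  est[exact_a] <- ttc_a[exact_a]
  est[exact_b] <- ttc_b[exact_b]
  sigma[exact_a | exact_b] <- 0
  tibble::tibble(estimate = est, wf = sigma / abs(est))
}
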