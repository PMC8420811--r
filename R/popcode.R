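# Encoding-decoding simulation: banks of Gaussian tuning curves encode the
# instantaneous optic variables as Poisson spike counts; maximum-likelihood
# decoding recovers the stimulus; gravity and size priors then turn the
# decoded optics into a TTC that can be matched against a hypothesis grid
# of candidate parabolas.

#' Population of Gaussian tuning curves
#'
#' `n_detectors` detectors with preferred values evenly spaced over
#' `[lo, hi]`, a common tuning width `sd` and peak expected spike count
#' `gain`. The mean response of detector i to stimulus s is
#' `gain * exp(-(s - pref_i)^2 / (2 * sd^2))`.
#'
#' @param lo,hi Stimulus range covered (in the stimulus' own units).
#' @param sd Tuning-curve standard deviation (> 0), same units.
#' @param n_detectors Number of detectors, default 33.
#' @param gain Peak expected spike count (> 0), default 50. Absolute
#'   decoding accuracy depends on this, which is why it is exposed.
#' @return A `tuning_population` list.
#' @export
tuning_population <- function(lo, hi, sd, n_detectors = 33, gain = 50) {
  stopifnot(hi > lo, sd > 0, n_detectors >= 2, gain >= 0)
  structure(
    list(
      preferred = seq(lo, hi, length.out = n_detectors),
      sd = sd,
      gain = gain,
      range = c(lo, hi)
    ),
    class = "tuning_population"
  )
}

#' Default detector populations for the three optic variables
#'
#' Ranges and tuning widths sized to the stimuli produced by the candidate
#' parabolas 200 ms after launch: retinal size 0.0024-0.0031 rad
#' (SD 0.00014, a 5% Weber fraction at mid-range), elevation angle
#' 0.045-0.085 rad (SD 0.00325) and its rate 0.2-0.45 rad/s (SD 0.01625).
#'
#' @inheritParams tuning_population
#' @return A named list of three [tuning_population()]s
#'   (`theta`, `gamma`, `gamma_dot`).
#' @export
default_populations <- function(n_detectors = 33, gain = 50) {
  list(
    theta = tuning_population(0.0024, 0.0031, 0.00014, n_detectors, gain),
    gamma = tuning_population(0.045, 0.085, 0.00325, n_detectors, gain),
    gamma_dot = tuning_population(0.2, 0.45, 0.01625, n_detectors, gain)
  )
}

#' Mean detector responses to a stimulus
#'
#' @param pop A [tuning_population()].
#' @param stimulus A single finite stimulus value.
#' @return Vector of mean spike counts, one per detector.
#' @export
tuning_response <- function(pop, stimulus) {
  stopifnot(is.numeric(stimulus), length(stimulus) == 1, is.finite(stimulus))
  pop$gain * exp(-(stimulus - pop$preferred)^2 / (2 * pop$sd^2))
}

#' Encode a stimulus as Poisson spike counts
#'
#' Independent Poisson draws around the mean responses: the population's
#' single-trial answer to the stimulus.
#'
#' @inheritParams tuning_response
#' @param seed Optional seed.
#' @return Integer vector of spike counts.
#' @export
encode_spikes <- function(pop, stimulus, seed = NULL) {
  with_seed(seed, rpois(length(pop$preferred), tuning_response(pop, stimulus)))
}

# Precompute the decode grid and per-grid-point expected rates.
decode_grid <- function(pop, grid_n) {
  grid <- seq(pop$range[1], pop$range[2], length.out = grid_n)
  f <- pop$gain *
    exp(-(outer(grid, pop$preferred, "-"))^2 / (2 * pop$sd^2))
  list(grid = grid, f = f, log_f = log(f), sum_f = rowSums(f))
}

# Vectorized ML decode of a trials x detectors count matrix.
decode_many <- function(pop, counts, grid_n = 1000) {
  dg <- decode_grid(pop, grid_n)
  ll <- counts %*% t(dg$log_f)
  ll <- sweep(ll, 2, dg$sum_f)
  dg$grid[max.col(ll, ties.method = "first")]
}

#' Maximum-likelihood stimulus decoding
#'
#' Maximizes the Poisson log likelihood
#' `sum_i (r_i * log f_i(s) - f_i(s))` over a dense grid of `grid_n`
#' stimulus values spanning the population's range. Ties break toward the
#' lower stimulus value.
#'
#' @param pop A [tuning_population()] with positive gain.
#' @param counts Nonnegative integer spike counts, one per detector.
#' @param grid_n Grid resolution, default 1000.
#' @return The decoded stimulus value.
#' @export
#' @examples
#' pop <- default_populations()$gamma
#' decode_mle(pop, round(tuning_response(pop, 0.065))) # ~0.065
decode_mle <- function(pop, counts, grid_n = 1000) {
  stopifnot(length(counts) == length(pop$preferred), all(counts >= 0))
  if (pop$gain == 0) {
    abort("Cannot decode: population gain is zero.")
  }
  decode_many(pop, matrix(counts, nrow = 1), grid_n)[1]
}

#' Candidate bank of hypothesis parabolas
#'
#' The hypothesis space of the prior-decoding experiment: every combination
#' of candidate flight time (TTC), gravity and ball size, each simulated as
#' a head-on eye-level vacuum parabola launched `z_init` metres away, and
#' probed noiselessly at `probe_time`. For each of the
#' `length(ttcs) * length(gravities) * length(sizes)` rows the bank records
#' the optic triplet `(theta, gamma, gamma_dot)`, the prior-free TTC
#' correlate `C = gamma_dot / (theta * cos(gamma))` (the GS expression with
#' the internalized terms removed) and the remaining flight time at the
#' probe.
#'
#' Defaults reproduce the 9 x 5 x 5 grid: TTC 1.8-2.2 s in steps of 0.05 s,
#' gravities at 0, +-5% and +-10% of 9.807 m/s^2, diameters at 0, +-2.5%
#' and +-5% of 0.074 m.
#'
#' @param probe_time Probe time in seconds (must lie within every candidate
#'   flight and on the `dt` grid). Default 0.2.
#' @param z_init Launch distance in metres, default 30.
#' @param ttcs,gravities,sizes Candidate axes.
#' @param dt Simulation step, default 0.01.
#' @return A `candidate_bank` tibble with columns `ttc, gravity, size,
#'   distance, theta, gamma, gamma_dot, correlate, remaining`.
#' @export
build_candidate_bank <- function(probe_time = 0.2, z_init = 30,
                                 ttcs = seq(1.8, 2.2, by = 0.05),
                                 gravities = c(8.826, 9.316, 9.807,
                                               10.297, 10.787),
                                 sizes = c(0.0703, 0.07215, 0.074,
                                           0.07585, 0.0777),
                                 dt = 0.01) {
  stopifnot(probe_time > 0, probe_time < min(ttcs))
  kin <- tidyr::expand_grid(ttc = ttcs, gravity = gravities)
  probe <- purrr::pmap_dfr(kin, function(ttc, gravity) {
    env <- env_spec(gravity = gravity)
    traj <- simulate_vacuum(make_head_on(z_init, ttc, env), env, dt = dt)
    stream <- project_optics(traj, baseball())
    i <- which(abs(stream$t - probe_time) < dt / 2)[1]
    if (is.na(i)) abort("`probe_time` does not fall on the sample grid.")
    tibble::tibble(
      ttc = ttc, gravity = gravity,
      distance = stream$distance[i],
      gamma = stream$gamma[i],
      gamma_dot = stream$gamma_dot[i]
    )
  })
  bank <- tidyr::expand_grid(probe, size = sizes) |>
    dplyr::mutate(
      theta = 2 * atan((.data$size / 2) / .data$distance),
      correlate = .data$gamma_dot / (.data$theta * cos(.data$gamma)),
      remaining = .data$ttc - probe_time
    ) |>
    dplyr::select("ttc", "gravity", "size", "distance", "theta",
                  "gamma", "gamma_dot", "correlate", "remaining")
  out <- tibble::new_tibble(bank, class = "candidate_bank")
  attr(out, "probe_time") <- probe_time
  attr(out, "z_init") <- z_init
  out
}

#' Prior-conditioned trajectory-identification experiment
#'
#' Simulates the full encode/decode loop. On each trial one of the
#' standard-gravity, standard-size candidates (one per candidate TTC) is
#' shown to the system: its optic triplet at the probe time is encoded as
#' Poisson spike counts and decoded back by maximum likelihood. The decoded
#' optics are then matched against the hypothesis space:
#'
#' * **prior-free** (`priors = NULL`): the decoded TTC correlate
#'   `C = gamma_dot / (theta * cos(gamma))` is compared with the correlate
#'   of all bank rows; rows within `margin` (relative) match.
#' * **with priors**: the decoded optics are calibrated into a TTC through
#'   the GS equation under the supplied priors and compared with the
#'   candidate remaining-TTC values; candidates within `margin` match.
#'
#' The reported TTC is drawn uniformly from the matched set (`scoring =
#' "draw"`; an empty set falls back to the nearest candidate), and a trial
#' is correct when the reported TTC equals the true one. With
#' `scoring = "contains"` a trial is instead correct whenever the matched
#' set contains the truth. With `margin = Inf` every candidate matches and
#' accuracy converges to chance (1/9 on the default grid).
#'
#' @param n_trials_per_ttc Trials per true TTC, default 1000.
#' @param priors A [prior_spec()] or `NULL` for the prior-free decoder.
#' @param margin Relative error margin for a candidate match, default 0.05.
#' @param bank A [build_candidate_bank()].
#' @param pops Detector populations, see [default_populations()].
#' @param scoring `"draw"` (default) or `"contains"`.
#' @param grid_n Decode-grid resolution.
#' @param seed Optional seed.
#' @return A `prior_experiment` object; see [tidy()] and [glance()]
#'   methods. The overall proportion of correct trials is in `$accuracy`.
#' @export
#' @examples
#' ex <- run_prior_experiment(n_trials_per_ttc = 50, priors = prior_spec(),
#'                            seed = 1)
#' glance(ex)
run_prior_experiment <- function(n_trials_per_ttc = 1000, priors = NULL,
                                 margin = 0.05,
                                 bank = build_candidate_bank(),
                                 pops = default_populations(),
                                 scoring = c("draw", "contains"),
                                 grid_n = 1000, seed = NULL) {
  stopifnot(margin > 0, n_trials_per_ttc >= 1)
  scoring <- match.arg(scoring)
  std_g <- 9.807
  std_s <- 0.074
  std <- bank[abs(bank$gravity - std_g) < 1e-9 &
                abs(bank$size - std_s) < 1e-9, ]
  if (nrow(std) == 0) {
    abort("The bank holds no standard-gravity, standard-size candidates.")
  }
  cand_remaining <- sort(unique(bank$remaining))

  with_seed(seed, {
    per_ttc <- purrr::map_dfr(seq_len(nrow(std)), function(j) {
      truth <- std[j, ]
      n <- n_trials_per_ttc
      est <- purrr::imap(
        c(theta = truth$theta, gamma = truth$gamma,
          gamma_dot = truth$gamma_dot),
        function(stim, var) {
          pop <- pops[[var]]
          f <- tuning_response(pop, stim)
          counts <- matrix(
            rpois(n * length(f), rep(f, times = n)),
            nrow = n, byrow = TRUE
          )
          decode_many(pop, counts, grid_n)
        }
      )
      if (is.null(priors)) {
        c_hat <- est$gamma_dot / (est$theta * cos(est$gamma))
        correct <- score_matches(c_hat, bank$correlate, bank$remaining,
                                 truth$remaining, margin, scoring)
      } else {
        ttc_hat <- (2 / priors$gravity) * (priors$size / est$theta) *
          est$gamma_dot / cos(est$gamma)
        correct <- score_matches(ttc_hat, cand_remaining, cand_remaining,
                                 truth$remaining, margin, scoring)
      }
      tibble::tibble(
        ttc = truth$ttc,
        n_trials = n,
        accuracy = mean(correct)
      )
    })
    structure(
      list(
        accuracy = sum(per_ttc$accuracy * per_ttc$n_trials) /
          sum(per_ttc$n_trials),
        by_ttc = per_ttc,
        chance = 1 / length(cand_remaining),
        n_trials_per_ttc = n_trials_per_ttc,
        margin = margin,
        priors = priors,
        scoring = scoring
      ),
      class = "prior_experiment"
    )
  })
}

# Match each estimate against candidate values within a relative margin and
# score the trial. `values` are the candidate quantities compared against,
# `labels` the remaining-TTC label attached to each candidate row.
score_matches <- function(estimates, values, labels, truth, margin,
                          scoring) {
  vapply(estimates, function(e) {
    hit <- abs(e - values) <= margin * abs(values)
    if (!any(hit)) {
      hit <- seq_along(values) == which.min(abs(e - values) / abs(values))
    }
    matched <- labels[hit]
    if (scoring == "contains") {
      any(abs(matched - truth) < 1e-9)
    } else {
      reported <- matched[sample.int(length(matched), 1)]
      abs(reported - truth) < 1e-9
    }
  }, logical(1))
}

#' Accuracy grid over prior assumptions
#'
#' Runs the identification experiment for the prior-free decoder, for the
#' correct priors, and for every single-axis perturbation of the priors
#' (each candidate gravity with the standard size, each candidate size with
#' standard gravity).
#'
#' @inheritParams run_prior_experiment
#' @return A `prior_grid` tibble with columns
#'   `decoder, gravity_prior, size_prior, accuracy, chance`.
#' @export
prior_accuracy_grid <- function(n_trials_per_ttc = 1000, margin = 0.05,
                                bank = build_candidate_bank(),
                                pops = default_populations(),
                                grid_n = 1000, seed = NULL) {
  gravities <- sort(unique(bank$gravity))
  sizes <- sort(unique(bank$size))
  run1 <- function(priors, decoder, gp, sp, s) {
    ex <- run_prior_experiment(
      n_trials_per_ttc = n_trials_per_ttc, priors = priors, margin = margin,
      bank = bank, pops = pops, grid_n = grid_n, seed = s
    )
    tibble::tibble(decoder = decoder, gravity_prior = gp, size_prior = sp,
                   accuracy = ex$accuracy, chance = ex$chance)
  }
  seeds <- if (is.null(seed)) {
    rep(list(NULL), 1 + length(gravities) + length(sizes))
  } else {
    as.list(seed + seq_len(1 + length(gravities) + length(sizes)))
  }
  rows <- list(run1(NULL, "sensory_only", NA_real_, NA_real_, seeds[[1]]))
  k <- 1
  for (g in gravities) {
    k <- k + 1
    rows <- c(rows, list(
      run1(prior_spec(gravity = g, size = 0.074), "gravity_axis", g, 0.074,
           seeds[[k]])
    ))
  }
  for (s in sizes) {
    k <- k + 1
    rows <- c(rows, list(
      run1(prior_spec(gravity = 9.807, size = s), "size_axis", 9.807, s,
           seeds[[k]])
    ))
  }
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "prior_grid")
}
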