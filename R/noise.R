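# Weber-noise Monte Carlo. Sensory noise is modelled per sample and per
# variable as x_chi = x + N(0, |x| * k_x): proportional (Weber) noise,
# independent across time samples, variables and simulations. Draws that
# would make the retinal size non-positive are redrawn (physical
# nonnegativity; at a 5% Weber fraction the redraw probability is ~0).

#' Inject Weber noise into an optical stream
#'
#' Returns the stream with `theta`, `gamma` and `gamma_dot` replaced by
#' their noisified versions. With all Weber fractions zero the input is
#' returned unchanged.
#'
#' @param stream An `optical_stream`.
#' @param cfg A [weber_config()] supplying the Weber fractions.
#' @param seed Optional seed, defaulting to `cfg$seed`.
#' @return An `optical_stream` with noisified angular variables.
#' @export
noisify <- function(stream, cfg = weber_config(), seed = cfg$seed) {
  with_seed(seed, {
    out <- stream
    out$theta <- redraw_positive(stream$theta, cfg$k_theta)
    out$gamma <- weber_draw(stream$gamma, cfg$k_gamma)
    out$gamma_dot <- weber_draw(stream$gamma_dot, cfg$k_gamma_dot)
    out
  })
}

weber_draw <- function(x, k) {
  if (k == 0) {
    return(x)
  }
  x + rnorm(length(x), 0, abs(x) * k)
}

redraw_positive <- function(x, k) {
  y <- weber_draw(x, k)
  bad <- which(!is.na(y) & y <= 0 & !is.na(x) & x > 0)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    y[bad] <- x[bad] + rnorm(length(bad), 0, x[bad] * k)
    bad <- bad[y[bad] <= 0]
    guard <- guard + 1
  }
  y
}

# Draw an n_samples x n_sims matrix of noisified copies of x.
weber_matrix <- function(x, k, n_sims, positive = FALSE) {
  n <- length(x)
  m <- x + matrix(rnorm(n * n_sims), n, n_sims) * (abs(x) * k)
  if (positive) {
    bad <- which(m <= 0 & x > 0)
    guard <- 0
    while (length(bad) > 0 && guard < 100) {
      xi <- x[(bad - 1) %% n + 1]
      m[bad] <- xi + rnorm(length(bad), 0, xi * k)
      bad <- bad[m[bad] <= 0]
      guard <- guard + 1
    }
  }
  m
}

new_wf_profile <- function(tbl, n_sims, flight_time) {
  out <- tibble::new_tibble(tbl, class = "wf_profile")
  attr(out, "n_sims") <- n_sims
  attr(out, "flight_time") <- flight_time
  out
}

#' Timewise Weber fraction of the GS output
#'
#' Runs `cfg$n_sims` independently noisified GS predictions for every time
#' sample of the stream and summarizes the precision of the output as a
#' timewise Weber fraction: `WF(t) = SD(TTC_chi(t)) / mean(TTC_chi(t))`.
#' Samples with undefined optics (the landing row of a head-on flight) are
#' dropped.
#'
#' @param stream An `optical_stream`.
#' @param priors A [prior_spec()].
#' @param cfg A [weber_config()]; `n_sims >= 100` is recommended for stable
#'   estimates.
#' @param seed Optional seed, defaulting to `cfg$seed`.
#' @return A `wf_profile` tibble with columns `t, mean_ttc, sd_ttc, wf`.
#' @export
#' @examples
#' traj <- simulate_vacuum(make_head_on(30, 2))
#' prof <- wf_timewise(project_optics(traj, baseball()),
#'                     cfg = weber_config(n_sims = 500, seed = 1))
#' max(prof$wf) # stays below 0.10
wf_timewise <- function(stream, priors = prior_spec(),
                        cfg = weber_config(), seed = cfg$seed) {
  keep <- stats::complete.cases(stream[c("theta", "gamma", "gamma_dot")])
  s <- stream[keep, ]
  n <- nrow(s)
  if (n == 0) abort("No samples with defined optics.")
  with_seed(seed, {
    th <- weber_matrix(s$theta, cfg$k_theta, cfg$n_sims, positive = TRUE)
    ga <- weber_matrix(s$gamma, cfg$k_gamma, cfg$n_sims)
    gd <- weber_matrix(s$gamma_dot, cfg$k_gamma_dot, cfg$n_sims)
    ttc <- (2 / priors$gravity) * (priors$size / th) * gd / cos(ga)
    m <- rowMeans(ttc)
    ssd <- sqrt(pmax(rowSums((ttc - m)^2), 0) / (cfg$n_sims - 1))
    if (any(abs(m) < 1e-9)) {
      warn("Mean predicted TTC ~ 0 at some samples; WF unstable there.")
    }
    tbl <- tibble::tibble(t = s$t, mean_ttc = m, sd_ttc = ssd, wf = ssd / m)
    new_wf_profile(tbl, n_sims = cfg$n_sims,
                   flight_time = attr(stream, "flight_time"))
  })
}

#' Weber fraction of the GS output fused with Tau
#'
#' Combines the GS Monte-Carlo precision from [wf_timewise()] with the Tau
#' cue via [combine_mle()]. Tau carries a fixed Weber fraction
#' (`cfg$k_tau`, default 10%) and is defined only while the image expands
#' (`theta_dot > 0`); during the receding phase the fused output falls back
#' to the GS cue alone. Wherever both cues are defined the fused Weber
#' fraction is at most the smaller of the two.
#'
#' @inheritParams wf_timewise
#' @return A `wf_profile` tibble with columns
#'   `t, wf_gs, wf_tau, wf_combined`.
#' @export
wf_combined <- function(stream, priors = prior_spec(),
                        cfg = weber_config(), seed = cfg$seed) {
  prof <- wf_timewise(stream, priors, cfg, seed = seed)
  tau_vals <- tau(stream)
  tau_at <- tau_vals$tau[match(round(prof$t, 9), round(tau_vals$t, 9))]
  wf_tau <- ifelse(is.na(tau_at), NA_real_, cfg$k_tau)
  fused <- combine_mle(prof$mean_ttc, prof$wf, tau_at, wf_tau)
  tbl <- tibble::tibble(
    t = prof$t,
    wf_gs = prof$wf,
    wf_tau = wf_tau,
    wf_combined = fused$wf
  )
  new_wf_profile(tbl, n_sims = attr(prof, "n_sims"),
                 flight_time = attr(prof, "flight_time"))
}

#' Representative Weber fraction over the central flight
#'
#' The summary used for the "about 7%" precision figure: the median of
#' `WF(t)` over the central portion of the flight, `t` in
#' `[lo * T, hi * T]`, pooled over one or several profiles.
#'
#' @param profiles A `wf_profile` or list of them.
#' @param lo,hi Fractional bounds of the central window (default 0.1-0.9).
#' @return A single Weber fraction.
#' @export
wf_representative <- function(profiles, lo = 0.1, hi = 0.9) {
  if (inherits(profiles, "wf_profile")) profiles <- list(profiles)
  vals <- unlist(lapply(profiles, function(p) {
    tt <- attr(p, "flight_time")
    w <- p$wf %||% p$wf_gs
    w[p$t >= lo * tt & p$t <= hi * tt]
  }))
  median(vals, na.rm = TRUE)
}
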