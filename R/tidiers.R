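#' Tidy a prior-decoding experiment
#'
#' One row per true candidate TTC with the proportion of correctly
#' identified trials.
#'
#' @param x A `prior_experiment`.
#' @param ... Unused.
#' @return A tibble `ttc, n_trials, accuracy`.
#' @export
tidy.prior_experiment <- function(x, ...) {
  x$by_ttc
}

#' Glance at a prior-decoding experiment
#'
#' @param x A `prior_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with the overall accuracy, the chance level,
#'   the decoder used, the match margin and the trial count.
#' @export
glance.prior_experiment <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    chance = x$chance,
    decoder = if (is.null(x$priors)) "sensory_only" else "with_priors",
    margin = x$margin,
    scoring = x$scoring,
    n_trials_per_ttc = x$n_trials_per_ttc
  )
}

#' @export
print.prior_experiment <- function(x, ...) {
  cat(sprintf(
    "<prior_experiment> %s decoder, margin %.3g: accuracy %.1f%% (chance %.1f%%)\n",
    if (is.null(x$priors)) "sensory-only" else "prior-calibrated",
    x$margin, 100 * x$accuracy, 100 * x$chance
  ))
  invisible(x)
}

#' Glance at a GS prediction series
#'
#' Headline accuracy figures of a `ttc_series`: the maximum and root mean
#' square of the signed prediction error and the error at the last sample
#' with defined optics.
#'
#' @param x A `ttc_series`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ttc_series <- function(x, ...) {
  err <- x$error[is.finite(x$error)]
  tibble::tibble(
    flight_time = attr(x, "flight_time"),
    max_abs_error = max(abs(err)),
    rmse = sqrt(mean(err^2)),
    final_error = err[length(err)],
    n_samples = length(err)
  )
}

#' Glance at a Weber-fraction profile
#'
#' @param x A `wf_profile` from [wf_timewise()] or [wf_combined()].
#' @param ... Unused.
#' @return A one-row tibble with the maximum and the central-flight median
#'   Weber fraction (columns are suffixed `_combined` when present).
#' @export
glance.wf_profile <- function(x, ...) {
  wf <- if ("wf" %in% names(x)) x$wf else x$wf_gs
  out <- tibble::tibble(
    max_wf = max(wf, na.rm = TRUE),
    representative_wf = wf_representative(
      structure(x, class = c("wf_profile", class(x)))
    ),
    n_sims = attr(x, "n_sims")
  )
  if ("wf_combined" %in% names(x)) {
    out$max_wf_combined <- max(x$wf_combined, na.rm = TRUE)
  }
  out
}
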