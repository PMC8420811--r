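# ggplot2 views of the package's result types. All return a ggplot object
# the caller can restyle.

#' Plot a GS prediction series
#'
#' Predicted TTC (solid) against the true remaining time (dashed) as a
#' function of time in flight.
#'
#' @param object A `ttc_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttc_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("t", "predicted", "true_remaining")],
    -"t", names_to = "series", values_to = "ttc"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$ttc,
                                   linetype = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_linetype_manual(
      values = c(predicted = "solid", true_remaining = "dashed")
    ) +
    ggplot2::labs(x = "time in flight (s)", y = "TTC (s)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an optical stream
#'
#' Faceted time courses of the egocentric variables.
#'
#' @param object An `optical_stream`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optical_stream <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                            names_to = "variable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time in flight (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Weber-fraction profile
#'
#' Timewise Weber fraction of the GS output (and of the GS + Tau fusion
#' when present), with the 10% Tau reference level dashed.
#'
#' @param object A `wf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wf_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  value_cols <- intersect(c("wf", "wf_gs", "wf_combined"), names(df))
  long <- tidyr::pivot_longer(df[c("t", value_cols)], -"t",
                              names_to = "cue", values_to = "wf")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$wf,
                                     colour = .data$cue)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.10, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "time in flight (s)", y = "Weber fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an accuracy grid over prior assumptions
#'
#' Identification accuracy as a function of the assumed gravity (standard
#' size) and assumed size (standard gravity), with the chance level and the
#' sensory-only decoder as dashed references.
#'
#' @param object A `prior_grid` from [prior_accuracy_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prior_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  axes <- dplyr::filter(df, .data$decoder %in% c("gravity_axis", "size_axis"))
  axes$prior_value <- ifelse(axes$decoder == "gravity_axis",
                             axes$gravity_prior, axes$size_prior)
  mle <- dplyr::filter(df, .data$decoder == "sensory_only")
  ggplot2::ggplot(axes, ggplot2::aes(.data$prior_value, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = df$chance[1], linetype = "dashed",
                        colour = "blue") +
    ggplot2::geom_hline(yintercept = mle$accuracy, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~decoder, scales = "free_x") +
    ggplot2::labs(x = "assumed prior value", y = "proportion correct") +
    ggplot2::theme_minimal()
}
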