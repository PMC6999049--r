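#' Plot fluorescence transients on a logarithmic time axis
#'
#' @param x a transient tibble (one or more samples).
#' @param log_time logarithmic time axis (the conventional OJIP view).
#' @param colour column mapped to colour, `"group"` by default.
#' @return a ggplot object.
#' @export
plot_transients <- function(x, log_time = TRUE, colour = "group") {
  p <- ggplot2::ggplot(x, ggplot2::aes(
    x = .data$time_us / 1e3, y = .data$fluor,
    colour = .data[[colour]], group = interaction(.data$label, .data$group)
  )) +
    ggplot2::geom_line(alpha = 0.9) +
    ggplot2::labs(x = "time since light onset (ms)",
                  y = "fluorescence (instrument units)", colour = colour) +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot normalised curves or difference kinetics
#'
#' For a long curve table ([normalize_curves()]) plots each curve facetted;
#' for a difference table ([difference_kinetics()]) plots the delta traces.
#'
#' @param curves a long curve tibble or difference tibble.
#' @param which optional subset of curve names.
#' @return a ggplot object.
#' @export
plot_curves <- function(curves, which = NULL) {
  if (!is.null(which)) {
    curves <- dplyr::filter(curves, .data$curve %in% which)
  }
  yvar <- if ("delta" %in% names(curves)) "delta" else "value"
  grp <- if ("label" %in% names(curves)) {
    ggplot2::aes(group = interaction(.data$label, .data$group),
                 colour = .data$group)
  } else if ("group" %in% names(curves)) {
    ggplot2::aes(group = .data$group, colour = .data$group)
  } else {
    ggplot2::aes()
  }
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time_us / 1e3, y = .data[[yvar]]
  )) +
    grp +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "time since light onset (ms)", y = yvar) +
    ggplot2::theme_minimal()
}

#' Plot MR 820 nm kinetics normalised to the onset value
#'
#' @param trace an MR trace tibble.
#' @return a ggplot object.
#' @export
plot_mr <- function(trace) {
  trace <- normalize_mr(trace)
  ggplot2::ggplot(trace, ggplot2::aes(
    x = .data$time_ms, y = .data$refl_rel, colour = .data$group,
    group = interaction(.data$label, .data$group)
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (ms)", y = "MR / MR_0", colour = "group") +
    ggplot2::theme_minimal()
}

#' Spider-style plot of parameters relative to the control
#'
#' Displays the [relative_to_control()] table: each treatment group's
#' parameters as fractions of the control mean (control = 1, dashed line).
#'
#' @param relative output of [relative_to_control()].
#' @return a ggplot object.
#' @export
plot_relative <- function(relative) {
  ggplot2::ggplot(relative, ggplot2::aes(
    x = .data$parameter, y = .data$relative, colour = .data$group,
    group = .data$group
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "fraction of control", colour = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @describeIn fit_i50 dose-response plot of the fit (log-dose axis, dose 0
#'   shown at the smallest non-zero dose / 10).
#' @param object an `i50_fit`.
#' @method autoplot i50_fit
#' @export
autoplot.i50_fit <- function(object, ...) {
  d <- object$data
  floor_dose <- min(d$dose[d$dose > 0]) / 10
  d$dose_plot <- pmax(d$dose, floor_dose)
  grid <- exp(seq(log(floor_dose), log(max(d$dose)), length.out = 100))
  pred <- if (!is.na(object$i50) && !is.na(object$hill_slope)) {
    tibble::tibble(
      dose = grid,
      response = object$top / (1 + (grid / object$i50)^object$hill_slope)
    )
  } else {
    NULL
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_plot, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (\u00b5M, log scale)", y = "response") +
    ggplot2::theme_minimal()
  if (!is.null(pred)) {
    p <- p + ggplot2::geom_line(
      data = pred, ggplot2::aes(x = .data$dose, y = .data$response),
      colour = "firebrick"
    )
  }
  if (!is.na(object$i50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$i50,
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}
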