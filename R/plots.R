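# ggplot2 helpers for the main result types.

#' Plot a titration or decay fit with its data
#'
#' @param object A `geci_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object: data points plus the fitted curve (log-x for
#'   calcium titrations).
#' @exportS3Method ggplot2::autoplot
autoplot.geci_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = switch(object$model,
                             hill_titration = "free [Ca2+] (nM)",
                             ph_titration = "pH",
                             neurite_decay = "arclength (um)",
                             "time (s)"),
                  y = switch(object$model,
                             neurite_decay = "normalized intensity",
                             "fluorescence (a.u.)"),
                  title = object$model,
                  subtitle = sprintf("R^2 = %.4f", object$r2)) +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged) && !is.null(object$fit)) {
    xs <- if (object$model == "hill_titration" && all(d$x > 0)) {
      exp(seq(log(min(d$x)), log(max(d$x)), length.out = n_grid))
    } else {
      seq(min(d$x), max(d$x), length.out = n_grid)
    }
    curve <- tibble::tibble(x = xs,
                            y = predict(object$fit, newdata = data.frame(x = xs)))
    p <- p + ggplot2::geom_line(data = curve, color = "firebrick")
  }
  if (object$model == "hill_titration") {
    p <- p + ggplot2::scale_x_log10()
  }
  p
}

#' Plot a distance-binned correlation profile
#'
#' @param profiles A [bin_correlation()] tibble, or several row-bound
#'   together with an added grouping column.
#' @param group Optional name of a grouping column (e.g. condition) for
#'   dodged bars.
#' @return A ggplot bar chart of mean PCC per distance bin.
#' @export
plot_correlation_profile <- function(profiles, group = NULL) {
  profiles$bin <- sprintf("%g-%g", profiles$bin_lo_um, profiles$bin_hi_um)
  profiles$bin <- factor(profiles$bin,
                         levels = unique(profiles$bin[order(profiles$bin_lo_um)]))
  if (is.null(group)) {
    ggplot2::ggplot(profiles,
                    ggplot2::aes(x = .data$bin, y = .data$mean_pcc)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = "centroid distance (um)",
                    y = "mean pairwise PCC") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(profiles,
                    ggplot2::aes(x = .data$bin, y = .data$mean_pcc,
                                 fill = .data[[group]])) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "centroid distance (um)",
                    y = "mean pairwise PCC") +
      ggplot2::theme_minimal()
  }
}

#' Plot an event-triggered average waveform with its SD band
#'
#' @param eta Tibble from [event_triggered_average()].
#' @param frame_rate Optional Hz; converts the x axis to seconds.
#' @return A ggplot object.
#' @export
plot_event_average <- function(eta, frame_rate = NULL) {
  x <- if (is.null(frame_rate)) eta$offset_frame else
    eta$offset_frame / frame_rate
  d <- tibble::tibble(x = x, mean = eta$mean, sd = eta$sd)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (is.null(frame_rate)) "offset (frames)" else
      "offset (s)", y = "dF/F0") +
    ggplot2::theme_minimal()
}

#' Stacked ROI trace plot
#'
#' @param traces Long tibble (`roi`, `frame` or `time_s`, `value`).
#' @param spacing Vertical offset between ROIs (default: data-driven).
#' @return A ggplot object with one offset line per ROI.
#' @export
plot_traces <- function(traces, spacing = NULL) {
  x <- if ("time_s" %in% names(traces)) "time_s" else "frame"
  spacing <- spacing %||% (2 * sd(traces$value))
  d <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::mutate(value = .data$value - mean(.data$value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(offset = .data$value +
                    spacing * match(.data$roi, sort(unique(.data$roi))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data$offset,
                                  group = .data$roi)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = if (x == "time_s") "time (s)" else "frame",
                  y = "ROI (offset traces)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
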