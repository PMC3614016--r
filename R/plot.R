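# Quick-look ggplot2 graphics for traces, fits and titration series.

#' Plot a stopped-flow trace
#'
#' @param trace A trace tibble (`time_s`, `signal_au`).
#' @param ... Additional traces to overlay, named.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, ...) {
  extra <- rlang::list2(...)
  traces <- c(list(trace = trace), extra)
  df <- dplyr::bind_rows(
    purrr::imap(traces, ~ dplyr::mutate(tibble::as_tibble(.x), trace = .y))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$signal_au,
                                   colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "FRET signal (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a clamp trace
#'
#' @param object A `clamp_trace` or `noisy_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clamp_trace <- function(object, ...) {
  plot_trace(object) + ggplot2::guides(colour = "none")
}

#' @rdname autoplot.clamp_trace
#' @export
autoplot.noisy_trace <- autoplot.clamp_trace

#' Autoplot a multi-exponential fit
#'
#' Data points with the fitted model curve overlaid.
#'
#' @param object An `exp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exp_fit <- function(object, ...) {
  df <- object$trace
  df$fitted <- predict(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$signal_au)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "FRET signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a titration break-point fit
#'
#' @param concentrations,ratios The titration data.
#' @param breakpoint_fit Output of [titration_breakpoint()].
#' @return A ggplot of the points with the fitted rise/plateau overlay.
#' @export
plot_breakpoint <- function(concentrations, ratios, breakpoint_fit) {
  df <- tibble::tibble(x = concentrations, y = ratios)
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "titrant (nM)", y = "amplitude ratio") +
    ggplot2::theme_minimal()
  if (isTRUE(breakpoint_fit$bounded)) {
    xx <- seq(min(df$x), max(df$x), length.out = 200)
    yy <- breakpoint_fit$intercept +
      breakpoint_fit$slope * pmin(xx, breakpoint_fit$breakpoint)
    g <- g + ggplot2::geom_line(data = tibble::tibble(x = xx, y = yy),
                                colour = "red") +
      ggplot2::geom_vline(xintercept = breakpoint_fit$breakpoint,
                          linetype = "dashed")
  }
  g
}
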