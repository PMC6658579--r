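#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stability map
#'
#' Gain-by-delay tiles colored by outcome: the divergence boundary of the
#' delayed feedback inverter.
#'
#' @param object A `stability_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$delay),
                                       y = factor(.data$gain),
                                       fill = .data$diverged)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#4477AA", `TRUE` = "#EE6677")) +
    ggplot2::labs(x = "feedback delay (steps)", y = "gain",
                  fill = "diverged",
                  title = "Stability of the delayed feedback inverter") +
    ggplot2::theme_minimal()
}

#' Plot a stochastic-drive trace
#'
#' Fitness and step-size sd over time: the form diffuses fast while
#' fitness is low and freezes once a high-fitness form is found.
#'
#' @param object A `drive_trace` from [run_drive()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drive_trace <- function(object, ...) {
  df <- tibble::tibble(t = object$t, fitness = object$f, sigma = object$sigma) |>
    tidyr::pivot_longer(c("fitness", "sigma"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL,
                  title = "Variance-modulated stochastic drive") +
    ggplot2::theme_minimal()
}

#' Plot a two-stage loop trace
#'
#' Per-cycle round-trip error of the forward/inverse pair on a log scale.
#'
#' @param object A `loop_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loop_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle,
                                       y = .data$roundtrip_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$converged), size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cycle", y = "round-trip error ||X(u_hat) - x|| / ||x||",
                  title = "Two-stage loop") +
    ggplot2::theme_minimal()
}

#' Plot a paired drive comparison
#'
#' Per-seed fitness-to-be under the modulated and matched-control
#' conditions, with pairing segments.
#'
#' @param object A `drive_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drive_comparison <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$f_plus)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$seed), color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "fitness-to-be (trailing-window mean f)",
                  title = "Estimate-modulated step size vs matched control") +
    ggplot2::theme_minimal()
}
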