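# floor under errors before taking reciprocals, so Q = 1/eps is always finite
EPS_FLOOR <- 1e-12

sample_norm <- function(v, norm) {
  switch(norm,
    L2 = sqrt(sum(v^2)),
    L1 = sum(abs(v)),
    stop("norm must be 'L2' or 'L1'", call. = FALSE)
  )
}

#' Estimator quality: how well the estimate tracks fitness
#'
#' The estimation error is the expected difference between estimate and
#' estimated, realized as a finite-window time average of the per-sample
#' norm `||x(t) - f(t)||` over the last `window` samples; quality is its
#' reciprocal, `Q_X = 1 / max(eps_X, 1e-12)` (the floor keeps a perfect
#' estimator's quality finite and is reported alongside).
#'
#' @param x_series,f_series Numeric series of equal length (>= `window`).
#' @param norm `"L2"` or `"L1"` (identical for scalar series).
#' @param window Number of trailing samples averaged; defaults to the full
#'   series.
#' @return A `quality_report` list with `eps_X`, `Q_X`, `norm`, `window`,
#'   `eps_floor`.
#' @examples
#' estimation_quality(c(1, 1.25), c(1, 1), norm = "L1")$eps_X
#' @export
estimation_quality <- function(x_series, f_series, norm = c("L2", "L1"),
                               window = length(x_series)) {
  norm <- match.arg(norm)
  if (length(x_series) == 0) stop("empty series", call. = FALSE)
  stopifnot(length(x_series) == length(f_series), window >= 1,
            window <= length(x_series))
  idx <- (length(x_series) - window + 1L):length(x_series)
  eps <- mean(abs(x_series[idx] - f_series[idx]))
  structure(list(eps_X = eps, Q_X = 1 / max(eps, EPS_FLOOR),
                 norm = norm, window = as.integer(window), eps_floor = EPS_FLOOR),
            class = "quality_report")
}

#' Inversion quality: how well the feedback loop undid the operator
#'
#' A perfect inversion would return a preimage whose forward image equals
#' the original: the error is `||x_i - X_i(u_hat)||`, and the quality its
#' reciprocal. Single-shot; average over a trace for the windowed variant.
#'
#' @param x_i The component output that was inverted.
#' @param comp The `estimator_component` that was inverted.
#' @param u_hat The approximate preimage (e.g. from [invert_fixed_point()]).
#' @param norm `"L2"` or `"L1"`.
#' @return A `quality_report` list with `eps_inv`, `Q_inv`, `norm`,
#'   `eps_floor`.
#' @export
inversion_quality <- function(x_i, comp, u_hat, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  stopifnot(inherits(comp, "estimator_component"))
  if (length(x_i) != comp$n) stop("x_i has the wrong dimension", call. = FALSE)
  eps <- sample_norm(x_i - apply_component(comp, u_hat), norm)
  structure(list(eps_inv = eps, Q_inv = 1 / max(eps, EPS_FLOOR),
                 norm = norm, eps_floor = EPS_FLOOR),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  if (!is.null(x$eps_X)) {
    cat(sprintf("<quality_report> eps_X = %.4g, Q_X = %.4g (%s, window %d)\n",
                x$eps_X, x$Q_X, x$norm, x$window))
  } else {
    cat(sprintf("<quality_report> eps_inv = %.4g, Q_inv = %.4g (%s)\n",
                x$eps_inv, x$Q_inv, x$norm))
  }
  invisible(x)
}
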