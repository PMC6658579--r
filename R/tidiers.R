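#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data %||%
NULL

#' Tidy an inversion result
#'
#' @param x An `inversion_result`.
#' @param ... Unused.
#' @return A tibble with one row per solution coordinate.
#' @export
tidy.inversion_result <- function(x, ...) {
  tibble::tibble(coordinate = seq_along(x$q), estimate = x$q)
}

#' @rdname tidy.inversion_result
#' @export
glance.inversion_result <- function(x, ...) {
  tibble::tibble(residual = x$residual, iterations = x$iterations,
                 converged = x$converged, diverged = x$diverged,
                 non_unique = x$non_unique)
}

#' Tidy a modulated-vs-control drive comparison
#'
#' @param x A `drive_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return `tidy()`: the per-seed tibble in long condition format;
#'   `glance()`: one row with the mean paired difference and the
#'   permutation p-value.
#' @export
tidy.drive_comparison <- function(x, ...) {
  x$per_seed |>
    tidyr::pivot_longer(c("f_plus_modulated", "f_plus_control"),
                        names_to = "condition", values_to = "f_plus",
                        names_prefix = "f_plus_")
}

#' @rdname tidy.drive_comparison
#' @export
glance.drive_comparison <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, p_value = x$p_value,
                 n_seeds = x$n_seeds, n_perm = x$n_perm)
}

#' Tidy a quality report
#'
#' @param x A `quality_report`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value` columns.
#' @export
tidy.quality_report <- function(x, ...) {
  vals <- x[vapply(x, is.numeric, logical(1))]
  tibble::tibble(metric = names(vals), value = unlist(vals, use.names = FALSE))
}

#' Tidy a run summary
#'
#' @param x A `run_summary`.
#' @param ... Unused.
#' @return `glance()`: one row of the run's scalar metrics.
#' @export
glance.run_summary <- function(x, ...) {
  m <- x$metrics[vapply(x$metrics, function(v) is.numeric(v) || is.logical(v),
                        logical(1))]
  dplyr::bind_cols(tibble::tibble(scenario = x$scenario, kind = x$kind,
                                  seed = x$seed),
                   tibble::as_tibble(m))
}

#' @export
print.drive_comparison <- function(x, ...) {
  cat(sprintf(paste0("<drive_comparison> %d paired seeds: mean f+ diff ",
                     "(modulated - control) = %.4g, one-sided sign-flip p = %.4g\n"),
              x$n_seeds, x$mean_diff, x$p_value))
  invisible(x)
}
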