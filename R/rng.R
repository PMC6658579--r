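#' Derive a reproducible sub-seed for a named random stream
#'
#' One root seed drives a whole scenario, but the modules (world drift,
#' estimator construction, stochastic drive, channel noise, permutation
#' tests) each get their own stream so that any one of them can be re-run
#' in isolation with identical draws. Streams are derived by a documented
#' integer hash: a polynomial character hash of the stream name combined
#' with the root seed by a multiplicative congruential step, everything
#' modulo 2^31 - 1 (so the result is always a valid `set.seed()` input).
#'
#' @param root_seed Integer root seed for the run.
#' @param stream Character scalar naming the stream, e.g. `"world"`,
#'   `"estimator"`, `"drive"`, `"channel"`, `"perm"`.
#' @return A positive integer seed, strictly below 2^31.
#' @examples
#' stream_seed(1, "world")
#' stream_seed(1, "drive")
#' @export
stream_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1, is.finite(root_seed))
  stopifnot(is.character(stream), length(stream) == 1, nzchar(stream))
  m <- 2147483647 # 2^31 - 1; all intermediates stay exactly representable
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  s <- ((abs(root_seed) %% m) * 69069 + h + 1) %% m
  as.integer(if (s == 0) 1 else s)
}
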