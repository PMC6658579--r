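#' Settings for the switched two-stage loop
#'
#' One estimator component is used in two alternating roles: stage 1 runs
#' it forward (producing the estimate `x_i` into a buffer), stage 2 places
#' the same instance in the feedback path of the high-gain inverter
#' (producing the communicable signal `u_hat` into a second buffer).
#' Buffers are sample-and-hold: each changes only at its own stage
#' boundary, so the loop tolerates the stages not running simultaneously.
#' The cycle period defaults to 0.1 time units — roughly ten switches per
#' unit time, echoing switching rates discussed for cortical processing —
#' and is a parameter, not a claim.
#'
#' @param cycle_period Positive real; duration of one full cycle.
#' @param duty Fraction of the cycle spent in stage 1, in (0, 1).
#' @param mode `"external_input"` (a fresh input each cycle) or
#'   `"internal_dialogue"` (stage-2 output feeds the next stage 1).
#' @param inversion An [inversion_config()] used by stage 2.
#' @param drift_within_cycle If `TRUE`, parameter drift also happens
#'   between stage 1 and stage 2 of a cycle, reproducing the small error
#'   from the two uses not being simultaneous. Default `FALSE`: drift is
#'   frozen within a cycle and applied at cycle boundaries.
#' @return A `loop_config`.
#' @export
loop_config <- function(cycle_period = 0.1, duty = 0.5,
                        mode = c("external_input", "internal_dialogue"),
                        inversion = inversion_config(),
                        drift_within_cycle = FALSE) {
  mode <- match.arg(mode)
  stopifnot(cycle_period > 0, duty > 0, duty < 1,
            inherits(inversion, "inversion_config"))
  structure(list(cycle_period = cycle_period, duty = duty, mode = mode,
                 inversion = inversion, drift_within_cycle = drift_within_cycle),
            class = "loop_config")
}

#' Create empty sample-and-hold buffers
#'
#' @param m,n Input and output dimension of the component served.
#' @return A `loop_buffers` object with `x_buf`, `u_buf` and their
#'   last-update times (`NA` until first written).
#' @export
loop_buffers <- function(m, n = m) {
  structure(list(x_buf = rep(NA_real_, n), u_buf = rep(NA_real_, m),
                 x_buf_time = NA_real_, u_buf_time = NA_real_),
            class = "loop_buffers")
}

#' Stage 1: forward estimation into the x buffer
#'
#' Applies the component to the input and latches the result in `x_buf`;
#' `u_buf` is untouched (buffer discipline).
#'
#' @param comp An `estimator_component`.
#' @param u_in Input vector of length `comp$m`.
#' @param buffers A [loop_buffers()].
#' @param time Time stamp recorded for the write.
#' @return The updated `loop_buffers`.
#' @export
run_stage1 <- function(comp, u_in, buffers, time = NA_real_) {
  stopifnot(inherits(buffers, "loop_buffers"))
  buffers$x_buf <- apply_component(comp, u_in)
  buffers$x_buf_time <- time
  buffers
}

#' Stage 2: feedback inversion into the u buffer
#'
#' Places the same component instance in the inverter's feedback path and
#' latches the approximate preimage of `x_buf` in `u_buf`; `x_buf` is
#' untouched. If the inversion diverges, `u_buf` holds its previous value
#' (sample-and-hold on failure) and the result carries the flag.
#'
#' @param comp The same `estimator_component` used in stage 1.
#' @param buffers A [loop_buffers()] with `x_buf` populated.
#' @param inv_cfg An [inversion_config()].
#' @param time Time stamp recorded for the write.
#' @return A list with elements `buffers` and `result` (an
#'   `inversion_result`).
#' @export
run_stage2 <- function(comp, buffers, inv_cfg = inversion_config(), time = NA_real_) {
  stopifnot(inherits(buffers, "loop_buffers"))
  if (anyNA(buffers$x_buf)) stop("x_buf is not populated; run stage 1 first", call. = FALSE)
  res <- invert_operator(as_operator(comp), buffers$x_buf, inv_cfg)
  if (!res$diverged) {
    buffers$u_buf <- res$q
    buffers$u_buf_time <- time
  }
  list(buffers = buffers, result = res)
}

new_loop_trace <- function(rows, mode, comp, buffers) {
  out <- dplyr::bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "final_component") <- comp
  attr(out, "final_buffers") <- buffers
  class(out) <- c("loop_trace", class(out))
  out
}

loop_cycle_row <- function(cycle, time, u_in, buffers, res, comp_s1,
                           hash_s1, hash_s2) {
  # round trip is judged against the stage-1 parameters: if the component
  # drifted between the two stages, u_hat is an imperfect preimage of x and
  # the error below picks that nonstationarity up
  x <- buffers$x_buf
  rt <- sqrt(sum((apply_component(comp_s1, buffers$u_buf) - x)^2)) /
    max(sqrt(sum(x^2)), .Machine$double.eps)
  tibble::tibble(
    cycle = cycle, t = time,
    u_in = list(u_in), x = list(x), u_hat = list(buffers$u_buf),
    roundtrip_error = rt, residual = res$residual,
    converged = res$converged, diverged = res$diverged,
    param_hash = hash_s1, same_instance = identical(hash_s1, hash_s2)
  )
}

#' Run the two-stage loop on an external input stream
#'
#' Alternates stage 1 and stage 2 for `n_cycles`, drifting the component's
#' parameters at cycle boundaries (slowly, at its own timescale). Within a
#' cycle both stages use byte-identical parameters (asserted per cycle in
#' the trace, column `same_instance`) unless `drift_within_cycle` is set.
#'
#' @param comp An `estimator_component`.
#' @param input_stream One input per cycle: a function of the cycle index,
#'   a list of vectors, a matrix (rows = cycles), or a single vector
#'   recycled every cycle.
#' @param n_cycles Number of cycles (0 gives an empty trace).
#' @param cfg A [loop_config()].
#' @return A `loop_trace` tibble, one row per cycle: buffered `x` and
#'   `u_hat`, the per-cycle round-trip error
#'   `||X(u_hat) - x|| / ||x||`, inversion diagnostics and the parameter
#'   fingerprint. The drifted component and final buffers ride along as
#'   attributes.
#' @export
run_external <- function(comp, input_stream, n_cycles, cfg = loop_config()) {
  stopifnot(inherits(comp, "estimator_component"), inherits(cfg, "loop_config"),
            n_cycles >= 0)
  get_input <- input_fetcher(input_stream, comp$m)
  buffers <- loop_buffers(comp$m, comp$n)
  rows <- vector("list", n_cycles)
  time <- 0
  for (cyc in seq_len(n_cycles)) {
    u_in <- get_input(cyc)
    comp_s1 <- comp
    h1 <- component_hash(comp)
    buffers <- run_stage1(comp, u_in, buffers, time + cfg$duty * cfg$cycle_period)
    if (cfg$drift_within_cycle) {
      comp <- drift_parameters(comp, cfg$duty * cfg$cycle_period)
    }
    h2 <- component_hash(comp)
    st2 <- run_stage2(comp, buffers, cfg$inversion, time + cfg$cycle_period)
    buffers <- st2$buffers
    rows[[cyc]] <- loop_cycle_row(cyc, time + cfg$cycle_period, u_in, buffers,
                                  st2$result, comp_s1, h1, h2)
    dt_rest <- if (cfg$drift_within_cycle) (1 - cfg$duty) * cfg$cycle_period else cfg$cycle_period
    if (comp$drift_sd > 0) comp <- drift_parameters(comp, dt_rest)
    time <- time + cfg$cycle_period
  }
  new_loop_trace(rows, "external_input", comp, buffers)
}

input_fetcher <- function(input_stream, m) {
  if (is.function(input_stream)) return(function(cyc) input_stream(cyc))
  if (is.list(input_stream)) return(function(cyc) input_stream[[cyc]])
  if (is.matrix(input_stream)) return(function(cyc) input_stream[cyc, ])
  if (is.numeric(input_stream) && length(input_stream) == m) {
    return(function(cyc) input_stream)
  }
  stop("input_stream must be a function, list, matrix, or single input vector",
       call. = FALSE)
}

#' Run the self-feeding internal dialogue
#'
#' Stage-2 output becomes the next cycle's stage-1 input: the loop's
#' communicable signal folds back to provide its own input, like a
#' two-stroke engine alternating fill and ignition. With a stationary
#' component the sequence of `u_hat` converges to a fixed point of the
#' finite-gain round trip; with a drifting component it keeps moving,
#' tracking the drift. A diverged inversion truncates nothing: the held
#' buffer is re-used, and the cycle is flagged.
#'
#' @param comp An `estimator_component` (square, so the output can be fed
#'   back as input).
#' @param u_init Initial stage-1 input.
#' @param n_cycles Number of cycles.
#' @param cfg A [loop_config()] with `mode = "internal_dialogue"`.
#' @return A `loop_trace` tibble with an additional `delta_u` column,
#'   `||u_hat(c) - u_hat(c-1)||` (`NA` for the first cycle).
#' @export
run_internal_dialogue <- function(comp, u_init, n_cycles,
                                  cfg = loop_config(mode = "internal_dialogue")) {
  stopifnot(inherits(comp, "estimator_component"), n_cycles >= 0)
  if (cfg$mode != "internal_dialogue") {
    stop("cfg$mode must be 'internal_dialogue'", call. = FALSE)
  }
  if (comp$m != comp$n) stop("internal dialogue needs a square component", call. = FALSE)
  buffers <- loop_buffers(comp$m, comp$n)
  u <- u_init
  u_prev <- NULL
  rows <- vector("list", n_cycles)
  time <- 0
  for (cyc in seq_len(n_cycles)) {
    h1 <- component_hash(comp)
    buffers <- run_stage1(comp, u, buffers, time + cfg$duty * cfg$cycle_period)
    st2 <- run_stage2(comp, buffers, cfg$inversion, time + cfg$cycle_period)
    buffers <- st2$buffers
    row <- loop_cycle_row(cyc, time + cfg$cycle_period, u, buffers, st2$result,
                          comp, h1, component_hash(comp))
    row$delta_u <- if (is.null(u_prev)) NA_real_ else sqrt(sum((buffers$u_buf - u_prev)^2))
    rows[[cyc]] <- row
    u_prev <- buffers$u_buf
    u <- buffers$u_buf # fold back
    if (comp$drift_sd > 0) comp <- drift_parameters(comp, cfg$cycle_period)
    time <- time + cfg$cycle_period
  }
  new_loop_trace(rows, "internal_dialogue", comp, buffers)
}
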