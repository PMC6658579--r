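#' Wrap a forward map as a generic operator
#'
#' The feedback inverter only ever calls `forward`, so anything evaluable
#' can be inverted: an [make_component()] (including `blackbox` kind) or a
#' plain function with declared dimensions.
#'
#' @param x An `estimator_component` or a function of one numeric vector.
#' @param m_in,m_out Dimensions, required when `x` is a function.
#' @param ... Unused.
#' @return A `generic_operator` with fields `forward`, `m_in`, `m_out`.
#' @export
as_operator <- function(x, ...) UseMethod("as_operator")

#' @rdname as_operator
#' @export
as_operator.estimator_component <- function(x, ...) {
  comp <- x
  structure(list(forward = function(q) apply_component(comp, q),
                 m_in = comp$m, m_out = comp$n),
            class = "generic_operator")
}

#' @rdname as_operator
#' @export
as_operator.function <- function(x, m_in, m_out = m_in, ...) {
  stopifnot(m_in >= 1, m_out >= 1)
  structure(list(forward = x, m_in = as.integer(m_in), m_out = as.integer(m_out)),
            class = "generic_operator")
}

#' @rdname as_operator
#' @export
as_operator.generic_operator <- function(x, ...) x

#' Settings for the high-gain feedback inverter
#'
#' The inverter realizes the approximate inverse of an operator `S` by the
#' feedback circuit `q = G (p - S q)` with `G = gain * B`: the amplifier
#' amplifies the difference between the target `p` and the fed-back `S q`.
#' Two realizations are provided: `fixed_point` iterates the circuit to its
#' equilibrium within one time step (the idealized algorithm), `dynamical`
#' relaxes toward it in explicit time with an optional transmission delay
#' in the feedback path (for stability analysis).
#'
#' @param gain Positive amplifier gain `g`. Larger gain means a more exact
#'   inverse (error scales as `1/g`) but slower, stiffer dynamics.
#' @param preconditioner `"identity"`, `"transpose_linearization"` (the
#'   transpose of a finite-difference linearization of `S` at `q = 0`,
#'   scaled by its largest singular value squared; gives gradient-like
#'   convergence toward the minimum-distance solution for non-square `S`),
#'   or an explicit matrix `B`.
#' @param mode `"fixed_point"` or `"dynamical"`.
#' @param damping Maximum relaxation step in (0, 1] for fixed-point mode;
#'   the effective step is reduced by backtracking whenever the circuit
#'   residual would grow, so high gains stay stable.
#' @param tol Convergence tolerance on the update norm, relative to
#'   `1 + ||q||`.
#' @param max_iter Iteration cap.
#' @param delay_steps Non-negative integer; feedback transmission delay of
#'   the dynamical mode, in steps.
#' @param relax_step Positive step of the dynamical relaxation.
#' @param fd_step Finite-difference step for the linearized preconditioner.
#' @param keep_trajectory Record the iterate trajectory?
#' @param divergence_factor Declare divergence when
#'   `||q|| > divergence_factor * (1 + ||p||)`.
#' @param divergence_run Declare divergence after this many consecutive
#'   residual increases (dynamical mode).
#' @return An `inversion_config`.
#' @export
inversion_config <- function(gain = 100, preconditioner = "identity",
                             mode = c("fixed_point", "dynamical"),
                             damping = 0.5, tol = 1e-10, max_iter = 10000L,
                             delay_steps = 0L, relax_step = 0.05,
                             fd_step = 1e-6, keep_trajectory = FALSE,
                             divergence_factor = 1e6, divergence_run = 50L) {
  mode <- match.arg(mode)
  stopifnot(gain > 0, damping > 0, damping <= 1, tol > 0, max_iter >= 1,
            delay_steps >= 0, relax_step > 0, fd_step > 0)
  structure(list(gain = gain, preconditioner = preconditioner, mode = mode,
                 damping = damping, tol = tol, max_iter = as.integer(max_iter),
                 delay_steps = as.integer(delay_steps), relax_step = relax_step,
                 fd_step = fd_step, keep_trajectory = keep_trajectory,
                 divergence_factor = divergence_factor,
                 divergence_run = as.integer(divergence_run)),
            class = "inversion_config")
}

# Resolve the preconditioner to a matrix (or NULL for identity).
precond_matrix <- function(S, cfg) {
  B <- cfg$preconditioner
  if (is.matrix(B)) return(B)
  if (identical(B, "identity")) {
    if (S$m_in != S$m_out) {
      stop("identity preconditioner requires a square operator; use ",
           "'transpose_linearization'", call. = FALSE)
    }
    return(NULL)
  }
  if (identical(B, "transpose_linearization")) {
    q0 <- rep(0, S$m_in)
    f0 <- S$forward(q0)
    J <- vapply(seq_len(S$m_in), function(j) {
      qj <- q0
      qj[j] <- cfg$fd_step
      (S$forward(qj) - f0) / cfg$fd_step
    }, numeric(S$m_out))
    J <- matrix(J, nrow = S$m_out)
    t(J) / max(svd(J)$d)^2
  } else {
    stop("unknown preconditioner", call. = FALSE)
  }
}

new_inversion_result <- function(q, p, S, iterations, converged, diverged,
                                 trajectory = NULL, non_unique = FALSE) {
  res <- tryCatch(sqrt(sum((p - S$forward(q))^2)), error = function(e) NA_real_)
  structure(list(q = q, residual = res, iterations = iterations,
                 converged = converged && !diverged, diverged = diverged,
                 trajectory = trajectory, non_unique = non_unique),
            class = "inversion_result")
}

#' Invert an operator through the feedback circuit, to equilibrium
#'
#' Iterates `q <- (1 - eta) q + eta * g * B * (p - S q)` from `q0 = 0`,
#' with `eta` backtracked from `damping` whenever the circuit residual
#' `||g B (p - S q) - q||` would grow (the found step is carried to the
#' next iteration). At the fixed point the circuit equation
#' `q = g B (p - S q)` holds to tolerance, so for large gain `q` is an
#' approximate `S^{-1} p`: for scalar linear `S = s` the equilibrium is
#' exactly `g p / (1 + g s)`.
#'
#' @param S Anything accepted by [as_operator()].
#' @param p Numeric target vector of length `S$m_out`.
#' @param cfg An [inversion_config()] with `mode = "fixed_point"`.
#' @return An `inversion_result`: the solution `q`, the forward residual
#'   `||p - S q||`, iteration count and convergence/divergence flags.
#' @examples
#' S <- as_operator(function(q) 2 * q, m_in = 1)
#' invert_fixed_point(S, 1, inversion_config(gain = 100))$q # 100/201
#' @export
invert_fixed_point <- function(S, p, cfg = inversion_config()) {
  S <- as_operator(S)
  stopifnot(inherits(cfg, "inversion_config"))
  if (length(p) != S$m_out) stop("p has the wrong dimension", call. = FALSE)
  B <- precond_matrix(S, cfg)
  G <- function(v) if (is.null(B)) cfg$gain * v else cfg$gain * drop(B %*% v)
  circuit <- function(q) G(p - S$forward(q)) - q # zero at equilibrium
  q <- rep(0, S$m_in)
  traj <- if (cfg$keep_trajectory) list(q) else NULL
  eta <- cfg$damping
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  r <- circuit(q)
  rn <- sqrt(sum(r^2))
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    step <- min(cfg$damping, 2 * eta)
    repeat {
      q_new <- q + step * r
      r_new <- tryCatch(circuit(q_new), error = function(e) rep(NaN, length(q)))
      rn_new <- sqrt(sum(r_new^2))
      if (is.finite(rn_new) && rn_new <= rn) break
      step <- step / 2
      if (step < 1e-16) break
    }
    if (!all(is.finite(q_new)) || step < 1e-16) {
      diverged <- !all(is.finite(q_new))
      break
    }
    eta <- step
    delta <- sqrt(sum((q_new - q)^2))
    q <- q_new
    r <- r_new
    rn <- rn_new
    if (cfg$keep_trajectory) traj <- c(traj, list(q))
    if (sqrt(sum(q^2)) > cfg$divergence_factor * (1 + sqrt(sum(p^2)))) {
      diverged <- TRUE
      break
    }
    if (delta <= cfg$tol * (1 + sqrt(sum(q^2)))) {
      converged <- TRUE
      break
    }
  }
  new_inversion_result(q, p, S, iter, converged, diverged, traj,
                       non_unique = S$m_out < S$m_in)
}

#' Invert an operator through the feedback circuit, in explicit time
#'
#' Integrates `q(t+1) = q(t) + relax_step * (-q(t) + g B (p - S q(t - d)))`
#' with a circular history buffer of length `delay_steps`. Unlike the
#' fixed-point mode there is no step safeguard: with enough gain or delay
#' the loop genuinely goes unstable, which is the point — divergence is
#' detected (norm blow-up, non-finite iterates, or a long run of growing
#' residuals) and flagged.
#'
#' @inheritParams invert_fixed_point
#' @return An `inversion_result`.
#' @export
invert_dynamical <- function(S, p, cfg = inversion_config(mode = "dynamical")) {
  S <- as_operator(S)
  stopifnot(inherits(cfg, "inversion_config"))
  if (length(p) != S$m_out) stop("p has the wrong dimension", call. = FALSE)
  B <- precond_matrix(S, cfg)
  G <- function(v) if (is.null(B)) cfg$gain * v else cfg$gain * drop(B %*% v)
  d <- cfg$delay_steps
  q <- rep(0, S$m_in)
  hist <- matrix(0, nrow = d + 1L, ncol = S$m_in) # circular buffer of past q
  traj <- if (cfg$keep_trajectory) list(q) else NULL
  converged <- FALSE
  diverged <- FALSE
  grow_run <- 0L
  small_run <- 0L
  res_prev <- Inf
  pn <- sqrt(sum(p^2))
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    # current q is q_{iter-1}; feedback sees q_{iter-1-d} (zero before start)
    q_del <- hist[(iter - 1L - d) %% (d + 1L) + 1L, ]
    drive <- tryCatch(G(p - S$forward(q_del)), error = function(e) rep(NaN, length(q)))
    q_new <- q + cfg$relax_step * (-q + drive)
    if (!all(is.finite(q_new))) {
      diverged <- TRUE
      q_new <- q
      break
    }
    res <- sqrt(sum((p - S$forward(q_new))^2))
    grow_run <- if (is.finite(res) && res > res_prev * (1 + 1e-12)) grow_run + 1L else 0L
    res_prev <- res
    delta <- sqrt(sum((q_new - q)^2))
    q <- q_new
    hist[iter %% (d + 1L) + 1L, ] <- q
    if (cfg$keep_trajectory) traj <- c(traj, list(q))
    if (sqrt(sum(q^2)) > cfg$divergence_factor * (1 + pn) ||
        grow_run >= cfg$divergence_run) {
      diverged <- TRUE
      break
    }
    # a single small update is meaningless under delay (the loop can sit on
    # a quasi-equilibrium plateau for a whole delay window before the next
    # kick arrives): require small updates across a full window, after the
    # delayed feedback has cycled through at least once
    small_run <- if (delta <= cfg$tol * (1 + sqrt(sum(q^2)))) small_run + 1L else 0L
    if (iter > 2L * (d + 1L) && small_run >= d + 2L) {
      converged <- TRUE
      break
    }
  }
  new_inversion_result(q, p, S, iter, converged, diverged, traj,
                       non_unique = S$m_out < S$m_in)
}

#' Invert with the mode named in the configuration
#'
#' @inheritParams invert_fixed_point
#' @export
invert_operator <- function(S, p, cfg = inversion_config()) {
  if (cfg$mode == "dynamical") invert_dynamical(S, p, cfg) else invert_fixed_point(S, p, cfg)
}

#' Exact inverse of a linear-monotone map (test oracle)
#'
#' Returns `A^{-1} (phi^{-1}(p) - b)`, the closed-form inverse of the
#' `phi(A u + b)` family. This is a verification oracle: the simulator's
#' loops never call it, since the theory's claim is that inversion is
#' achieved by feedback, not analytically.
#'
#' @param A Square invertible matrix.
#' @param b Bias vector.
#' @param phi Nonlinearity token (`"identity"` or `"leaky_softplus"`).
#' @param p Target vector.
#' @return The exact preimage of `p`.
#' @export
analytic_linear_oracle <- function(A, b, phi, p) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (rcond(A) < 1e-12) stop("A is numerically singular", call. = FALSE)
  drop(solve(A, phi_inverse(phi, p) - b))
}

#' Map the stability of the delayed feedback inverter over a grid
#'
#' Runs [invert_dynamical()] for every (gain, delay) pair on a fixed probe
#' target and tabulates the outcome. With no delay the loop converges for
#' any gain below the relaxation stability limit; past a gain-dependent
#' delay it oscillates and diverges. For each gain, once divergence
#' appears it should persist at all larger delays; violations of that
#' monotone pattern are counted in the `monotone_violations` attribute.
#'
#' @param S Anything accepted by [as_operator()].
#' @param gains,delays Numeric grids (non-empty).
#' @param cfg Base [inversion_config()]; gain/delay are overridden per cell.
#' @param probe Target vector `p`; default a vector of ones.
#' @return A tibble with columns `gain`, `delay`, `converged`, `diverged`,
#'   `settle_steps` (iterations when converged, `NA` otherwise) and
#'   `residual`.
#' @export
stability_map <- function(S, gains, delays, cfg = inversion_config(mode = "dynamical"),
                          probe = NULL) {
  S <- as_operator(S)
  stopifnot(length(gains) >= 1, length(delays) >= 1)
  if (is.null(probe)) probe <- rep(1, S$m_out)
  grid <- tidyr::expand_grid(gain = as.numeric(gains), delay = as.integer(delays))
  rows <- purrr::pmap(grid, function(gain, delay) {
    cell <- cfg
    cell$gain <- gain
    cell$delay_steps <- delay
    cell$mode <- "dynamical"
    r <- invert_dynamical(S, probe, cell)
    tibble::tibble(gain = gain, delay = delay, converged = r$converged,
                   diverged = r$diverged,
                   settle_steps = if (r$converged) r$iterations else NA_integer_,
                   residual = r$residual)
  })
  out <- dplyr::bind_rows(rows)
  viol <- out |>
    dplyr::arrange(.data$gain, .data$delay) |>
    dplyr::group_by(.data$gain) |>
    dplyr::summarise(v = sum(diff(as.integer(.data$diverged)) < 0)) |>
    dplyr::pull(.data$v) |>
    sum()
  attr(out, "monotone_violations") <- viol
  class(out) <- c("stability_map", class(out))
  out
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> dim %d, residual %.3g, %d iter, %s\n",
              length(x$q), x$residual, x$iterations,
              if (x$diverged) "DIVERGED" else if (x$converged) "converged" else "not converged"))
  invisible(x)
}
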