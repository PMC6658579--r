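#' @keywords internal
"_PACKAGE"

# Coordinatewise nonlinearities. Every token must be strictly increasing and
# bijective on the reals with slope bounded below, so that components stay
# invertible and the feedback loop stays well conditioned.
phi_eval <- function(token, z) {
  switch(token,
    identity = z,
    # slope in (0.25, 1): a softplus leaking a linear floor, bijective on R
    leaky_softplus = 0.25 * z + 0.75 * softplus(z),
    stop("unknown nonlinearity: ", token, call. = FALSE)
  )
}

phi_slope <- function(token, z) {
  switch(token,
    identity = rep(1, length(z)),
    leaky_softplus = 0.25 + 0.75 * stats::plogis(z),
    stop("unknown nonlinearity: ", token, call. = FALSE)
  )
}

# numerically safe log(1 + exp(z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

# Inverse of the coordinatewise nonlinearity via safeguarded Newton; the
# slope floor (>= 0.25) makes this globally convergent and fast.
phi_inverse <- function(token, y) {
  if (token == "identity") return(y)
  vapply(y, function(yy) {
    z <- yy / 0.6
    for (i in 1:100) {
      fz <- phi_eval(token, z) - yy
      if (abs(fz) < 1e-14 * (1 + abs(yy))) break
      z <- z - fz / phi_slope(token, z)
    }
    z
  }, numeric(1))
}

#' Construct an estimator component
#'
#' A component is one forward-evaluable sub-operator of the fitness
#' estimator: `x_i = phi(A u_i + b)` with `A` an `n x m` matrix, `b` a bias
#' and `phi` a strictly increasing coordinatewise nonlinearity. Square
#' `linear_monotone` components are invertible by construction; their
#' condition number is capped at `cond_cap` (resampling, then spectral
#' clipping). A `blackbox` component wraps such a reference map but exposes
#' forward evaluation only, so feedback inversion is the only way to undo
#' it. Components drift slowly: every matrix and bias entry follows a
#' mean-reverting random walk around its construction-time value, with
#' timescale `drift_timescale` and stationary sd `drift_sd`.
#'
#' @param m,n Positive integers; input and output dimension.
#' @param kind `"linear_monotone"` or `"blackbox"`.
#' @param ensemble Matrix ensemble: `"gaussian"` (entries `N(0, 1/m)`),
#'   `"identity"`, or `"spd"` (symmetric positive definite, square only).
#' @param nonlinearity `"identity"` or `"leaky_softplus"`.
#' @param drift_timescale Positive real, in time units.
#' @param drift_sd Non-negative real; stationary sd of parameter drift.
#' @param cond_cap Condition-number cap for square components.
#' @param scale Scalar multiplying the drawn matrix (e.g. the identity
#'   ensemble with `scale = 2` gives the map `u -> 2 u`).
#' @param bias_sd Sd of the random bias draw.
#' @param id Character token naming the component.
#' @param seed Integer seed (stream `"estimator"`).
#' @param max_resample Resampling attempts before spectral clipping.
#' @return An `estimator_component`.
#' @examples
#' comp <- make_component(m = 2, seed = 1, ensemble = "identity")
#' apply_component(comp, c(0.3, -1.2))
#' @export
make_component <- function(m, n = m, kind = c("linear_monotone", "blackbox"),
                           ensemble = c("gaussian", "identity", "spd"),
                           nonlinearity = "identity",
                           drift_timescale = 100, drift_sd = 0,
                           cond_cap = 1e4, scale = 1, bias_sd = 0, id = "c1",
                           seed = 1, max_resample = 20) {
  kind <- match.arg(kind)
  ensemble <- match.arg(ensemble)
  stopifnot(m >= 1, n >= 1, m == round(m), n == round(n),
            drift_timescale > 0, drift_sd >= 0, cond_cap >= 1, bias_sd >= 0)
  set.seed(stream_seed(seed, paste0("estimator:", id)))
  draw <- function() {
    switch(ensemble,
      identity = {
        if (n != m) stop("identity ensemble requires n == m", call. = FALSE)
        diag(m)
      },
      gaussian = {
        A <- matrix(stats::rnorm(n * m, sd = 1 / sqrt(m)), n, m)
        if (n == m) {
          # shift so the symmetric part is >= 0.3 I: the map is then a
          # strongly monotone operator, the condition under which the
          # high-gain negative-feedback loop can actually invert it
          lam <- min(eigen((A + t(A)) / 2, symmetric = TRUE,
                           only.values = TRUE)$values)
          A <- A + (0.3 - min(lam, 0)) * diag(m)
        }
        A
      },
      spd = {
        if (n != m) stop("spd ensemble requires n == m", call. = FALSE)
        M <- matrix(stats::rnorm(m * m, sd = 1 / sqrt(m)), m, m)
        M %*% t(M) + 0.5 * diag(m)
      }
    )
  }
  A <- draw()
  if (n == m && ensemble == "gaussian") {
    tries <- 0
    while (kappa(A, exact = TRUE) > cond_cap && tries < max_resample) {
      A <- draw()
      tries <- tries + 1
    }
    if (kappa(A, exact = TRUE) > cond_cap) A <- clip_condition(A, cond_cap)
  }
  A <- scale * A
  b <- if (bias_sd > 0) stats::rnorm(n, sd = bias_sd) else rep(0, n)
  comp <- structure(
    list(id = id, m = as.integer(m), n = as.integer(n), kind = kind,
         A = A, b = b, A0 = A, b0 = b, nonlinearity = nonlinearity,
         drift_timescale = drift_timescale, drift_sd = drift_sd,
         cond_cap = cond_cap),
    class = "estimator_component"
  )
  comp
}

# clamp singular values so that cond(A) <= cap, preserving singular vectors
clip_condition <- function(A, cap) {
  sv <- svd(A)
  d <- pmax(sv$d, max(sv$d) / cap)
  sv$u %*% (d * t(sv$v))
}

#' Apply an estimator component forward
#'
#' Computes `x_i = phi(A u_i + b)`. For a `blackbox` component the same map
#' is evaluated, but no other part of the package ever reads its
#' parameters: inversion must go through the feedback loop.
#'
#' @param comp An `estimator_component`.
#' @param u Numeric input vector of length `comp$m`.
#' @return Numeric output vector of length `comp$n`.
#' @export
apply_component <- function(comp, u) {
  stopifnot(inherits(comp, "estimator_component"))
  if (length(u) != comp$m) {
    stop("input length ", length(u), " does not match component input dim ",
         comp$m, call. = FALSE)
  }
  phi_eval(comp$nonlinearity, drop(comp$A %*% u) + comp$b)
}

#' Bundle components into an estimator bank
#'
#' The bank aggregates component outputs into the scalar fitness estimate
#' `x = output_map(sum_i w_i * mean(x_i))`. The output map is a smooth
#' non-negative squashing; `"softplus"` (default, `output_map(0) = log 2`)
#' or `"relu"`.
#'
#' @param components List of [make_component()] objects.
#' @param weights Numeric vector, one weight per component.
#' @param output_map `"softplus"` or `"relu"`.
#' @return An `estimator_bank`.
#' @export
estimator_bank <- function(components, weights = rep(1, length(components)),
                           output_map = c("softplus", "relu")) {
  output_map <- match.arg(output_map)
  if (length(components) < 1) stop("bank needs at least one component", call. = FALSE)
  stopifnot(all(vapply(components, inherits, logical(1), "estimator_component")),
            length(weights) == length(components), all(is.finite(weights)))
  structure(list(components = components, weights = as.numeric(weights),
                 output_map = output_map),
            class = "estimator_bank")
}

#' Aggregate component outputs into the scalar fitness estimate
#'
#' @param bank An [estimator_bank()].
#' @param component_outputs List of numeric vectors, aligned with the
#'   bank's components.
#' @return Non-negative scalar estimate `x`.
#' @export
aggregate_estimate <- function(bank, component_outputs) {
  stopifnot(inherits(bank, "estimator_bank"))
  if (length(component_outputs) != length(bank$components)) {
    stop("component_outputs length does not match the bank", call. = FALSE)
  }
  s <- sum(bank$weights * vapply(component_outputs, mean, numeric(1)))
  switch(bank$output_map,
    softplus = softplus(s),
    relu = max(s, 0)
  )
}

#' Run the full sensing-to-estimate chain of a bank
#'
#' Splits `u` across components in order (each takes its next `m` inputs),
#' applies each, and aggregates.
#'
#' @param bank An [estimator_bank()].
#' @param u Numeric vector whose length is the sum of component input dims.
#' @return Scalar estimate `x`.
#' @export
estimate_fitness <- function(bank, u) {
  stopifnot(inherits(bank, "estimator_bank"))
  ms <- vapply(bank$components, `[[`, integer(1), "m")
  if (length(u) != sum(ms)) {
    stop("input length must equal the total component input dimension", call. = FALSE)
  }
  idx <- c(0, cumsum(ms))
  outs <- purrr::map2(bank$components, seq_along(ms),
                      function(cm, i) apply_component(cm, u[(idx[i] + 1):idx[i + 1]]))
  aggregate_estimate(bank, outs)
}

#' Drift a component's parameters by one slow step
#'
#' Every entry of `A` and `b` follows the exact mean-reverting
#' (Ornstein-Uhlenbeck) transition around its construction-time anchor,
#' with the component's `drift_timescale` and stationary sd `drift_sd`;
#' the condition cap is re-enforced by spectral clipping afterwards.
#' Consumes the current RNG state; with `drift_sd = 0` the component is
#' returned unchanged.
#'
#' @param comp An `estimator_component`.
#' @param dt Positive time step; should be much smaller than
#'   `drift_timescale` (a warning is raised otherwise).
#' @return The drifted `estimator_component`.
#' @export
drift_parameters <- function(comp, dt) {
  stopifnot(inherits(comp, "estimator_component"), dt > 0)
  if (comp$drift_sd == 0) return(comp)
  if (dt > comp$drift_timescale / 5) {
    warning("dt is not small relative to drift_timescale; drift is no longer slow",
            call. = FALSE)
  }
  a <- exp(-dt / comp$drift_timescale)
  s <- comp$drift_sd * sqrt(max(0, 1 - a^2))
  comp$A <- comp$A0 + a * (comp$A - comp$A0) +
    matrix(stats::rnorm(length(comp$A), sd = s), nrow(comp$A), ncol(comp$A))
  comp$b <- comp$b0 + a * (comp$b - comp$b0) + stats::rnorm(length(comp$b), sd = s)
  if (comp$n == comp$m && kappa(comp$A, exact = TRUE) > comp$cond_cap) {
    comp$A <- clip_condition(comp$A, comp$cond_cap)
  }
  comp
}

# a stable fingerprint of the parameters in play during a cycle
component_hash <- function(comp) rlang::hash(list(comp$A, comp$b, comp$nonlinearity))

#' @export
print.estimator_component <- function(x, ...) {
  cat(sprintf("<estimator_component '%s'> %s %dx%d, phi = %s, drift sd %g (tau %g)\n",
              x$id, x$kind, x$n, x$m, x$nonlinearity, x$drift_sd, x$drift_timescale))
  invisible(x)
}

#' @export
print.estimator_bank <- function(x, ...) {
  cat(sprintf("<estimator_bank> %d component(s), output_map = %s\n",
              length(x$components), x$output_map))
  invisible(x)
}
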