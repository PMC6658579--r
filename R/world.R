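#' Define a world with a multi-peak fitness landscape
#'
#' The "world" holds everything fitness depends on: the organism's own form
#' `theta` (a point in a `dim_form`-dimensional space of forms) and an
#' environment vector that drifts as a mean-reverting (Ornstein-Uhlenbeck)
#' process. Fitness is a sum of Gaussian bumps over form space, optionally
#' gated by the environment; it is always finite and non-negative.
#'
#' @param dim_form Positive integer, dimension of the organism's form.
#' @param dim_env Non-negative integer, dimension of the environment vector.
#' @param landscape List of bumps created by [bump()]; at least one.
#' @param env_timescale Positive real; mean-reversion timescale of the
#'   environment, in time units. `Inf` freezes the environment.
#' @param env_sd Non-negative real; stationary standard deviation of each
#'   environment coordinate.
#' @param env_gate Real; strength of the multiplicative environment gate on
#'   fitness, `exp(env_gate * mean(env))`. `0` (default) disables gating.
#' @param obs_noise_sd Non-negative real; sd of additive sensing noise.
#' @param dt Positive real; fast time step of the simulation.
#' @param init_scale Non-negative real; sd of the initial form draw.
#' @param init_mean Numeric vector of length `dim_form` (or scalar,
#'   recycled); mean of the initial form draw.
#' @return A `world_config` object (a validated list).
#' @examples
#' cfg <- world_config(dim_form = 2, landscape = list(bump(c(0, 0))))
#' w <- init_world(cfg, seed = 1)
#' evaluate_fitness(w, cfg)$f
#' @export
world_config <- function(dim_form = 2, dim_env = 0,
                         landscape = list(bump(rep(0, dim_form))),
                         env_timescale = 50, env_sd = 1, env_gate = 0,
                         obs_noise_sd = 0, dt = 0.01,
                         init_scale = 1, init_mean = 0) {
  stopifnot(dim_form >= 1, dim_form == round(dim_form))
  stopifnot(dim_env >= 0, dim_env == round(dim_env))
  if (length(landscape) < 1) stop("landscape must contain at least one bump", call. = FALSE)
  landscape <- lapply(landscape, function(b) {
    b <- as_bump(b)
    if (length(b$center) != dim_form) {
      stop("bump center length must equal dim_form", call. = FALSE)
    }
    b
  })
  stopifnot(env_timescale > 0, env_sd >= 0, obs_noise_sd >= 0, dt > 0, init_scale >= 0)
  init_mean <- rep_len(as.numeric(init_mean), dim_form)
  structure(
    list(dim_form = as.integer(dim_form), dim_env = as.integer(dim_env),
         landscape = landscape, env_timescale = env_timescale, env_sd = env_sd,
         env_gate = env_gate, obs_noise_sd = obs_noise_sd, dt = dt,
         init_scale = init_scale, init_mean = init_mean),
    class = "world_config"
  )
}

#' @rdname world_config
#' @param center Numeric vector in form space; peak location.
#' @param height Positive real; peak fitness contribution.
#' @param width Positive real; Gaussian width (sd) of the bump.
#' @export
bump <- function(center, height = 1, width = 1) {
  stopifnot(is.numeric(center), all(is.finite(center)), height > 0, width > 0)
  list(center = as.numeric(center), height = height, width = width)
}

as_bump <- function(b) {
  if (!is.list(b) || !all(c("center", "height", "width") %in% names(b))) {
    stop("each landscape entry must be a bump(center, height, width)", call. = FALSE)
  }
  bump(unlist(b$center), b$height, b$width)
}

#' Initialize the world state
#'
#' The form is drawn as `init_mean + init_scale * N(0, I)`; the environment
#' starts at zero (its stationary mean); time starts at zero.
#'
#' @param config A [world_config()].
#' @param seed Integer seed; the draw uses the `"world"` stream of
#'   [stream_seed()], so initialization is deterministic given the seed.
#' @return A `world_state` list with fields `theta`, `env`, `t`.
#' @export
init_world <- function(config, seed) {
  stopifnot(inherits(config, "world_config"))
  set.seed(stream_seed(seed, "world"))
  theta <- config$init_mean + config$init_scale * stats::rnorm(config$dim_form)
  structure(list(theta = theta, env = rep(0, config$dim_env), t = 0),
            class = "world_state")
}

#' Advance the environment by one time step
#'
#' The environment follows a mean-reverting random walk around zero with
#' timescale `env_timescale` and stationary sd `env_sd`. The update is the
#' exact discrete-time transition of the Ornstein-Uhlenbeck process:
#' `env' = a * env + env_sd * sqrt(1 - a^2) * xi`, `a = exp(-dt / tau)`,
#' so the stationary variance is exactly `env_sd^2` at any `dt`. The form
#' is unchanged; time advances by `dt`. Consumes the current RNG state.
#'
#' @param state A `world_state`.
#' @param config A [world_config()].
#' @return The advanced `world_state`.
#' @export
step_environment <- function(state, config) {
  stopifnot(inherits(state, "world_state"), inherits(config, "world_config"))
  if (config$dim_env > 0) {
    a <- exp(-config$dt / config$env_timescale)
    state$env <- a * state$env +
      config$env_sd * sqrt(max(0, 1 - a^2)) * stats::rnorm(config$dim_env)
  }
  state$t <- state$t + config$dt
  state
}

#' Evaluate fitness at the current state
#'
#' Each bump `j` contributes `height_j * exp(-||theta - center_j||^2 /
#' (2 width_j^2))`, multiplied by the environment gate
#' `exp(env_gate * mean(env))` when gating is enabled. The per-bump
#' contributions are the fitness components; the scalar fitness is their
#' sum (a monotone pooling, so `f >= 0` always). Deterministic: no RNG.
#'
#' @param state A `world_state`.
#' @param config A [world_config()].
#' @return A `fitness_value` list with scalar `f` and `components`, one
#'   per landscape bump.
#' @export
evaluate_fitness <- function(state, config) {
  stopifnot(inherits(state, "world_state"), inherits(config, "world_config"))
  gate <- if (config$dim_env > 0 && config$env_gate != 0) {
    exp(config$env_gate * mean(state$env))
  } else 1
  comps <- vapply(config$landscape, function(b) {
    d2 <- sum((state$theta - b$center)^2)
    gate * b$height * exp(-d2 / (2 * b$width^2))
  }, numeric(1))
  structure(list(f = sum(comps), components = as.list(comps)),
            class = "fitness_value")
}

#' Sense the world
#'
#' The sensed vector is the projection `u = (theta, env)` plus i.i.d.
#' zero-mean Gaussian noise with sd `obs_noise_sd`; with zero noise the
#' projection is returned exactly. Consumes the current RNG state.
#'
#' @param state A `world_state`.
#' @param config A [world_config()].
#' @return Numeric vector of length `dim_form + dim_env`.
#' @export
sense <- function(state, config) {
  stopifnot(inherits(state, "world_state"), inherits(config, "world_config"))
  u <- c(state$theta, state$env)
  if (config$obs_noise_sd > 0) u <- u + stats::rnorm(length(u), sd = config$obs_noise_sd)
  u
}
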