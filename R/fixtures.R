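#' Canonical scenario fixtures
#'
#' Returns one of the fully specified scenarios the package's property
#' suite runs end to end. Deterministic given `name` and `seed`.
#'
#' * `"scalar_linear"` — invert the scalar map `q -> 2 q` at target
#'   `p = 1` for gains 10, 100, 1000; the feedback solution has the closed
#'   form `g p / (1 + g s)`.
#' * `"square_monotone"` — invert a random well-conditioned 5x5 component
#'   with the leaky-softplus nonlinearity, gains 100 / 1000 / 10000.
#' * `"blackbox"` — the same map wrapped as forward-evaluable only.
#' * `"delayed_loop"` — dynamical inversion of the scalar map over a
#'   gain-by-delay grid; maps the stability boundary.
#' * `"two_bump_drive"` — the variance-modulation comparison: a form
#'   starting on a low fitness bump with a higher bump nearby, 20 paired
#'   seeds of modulated vs matched-mean-sigma control.
#' * `"dialogue_pair"` — two identical stationary agents, perfect
#'   channel, high gain, 12 turns.
#' * `"internal_dialogue"` — the self-feeding loop on a stationary
#'   symmetric positive-definite component, 800 cycles.
#'
#' @param name Fixture name (see above).
#' @param seed Integer root seed.
#' @return A `scenario_config`.
#' @export
generate_fixture <- function(name, seed = 1) {
  fixtures <- c("scalar_linear", "square_monotone", "blackbox", "delayed_loop",
                "two_bump_drive", "dialogue_pair", "internal_dialogue")
  if (!is.character(name) || length(name) != 1 || !name %in% fixtures) {
    stop("unknown fixture; available: ", paste(fixtures, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(seed)
  switch(name,
    scalar_linear = scenario_config(
      name = "scalar_linear", kind = "inversion", seed = seed,
      bank = list(components = list(default_component_spec(
        m = 1, ensemble = "identity", scale = 2, id = "s2"))),
      run = list(gains = c(10, 100, 1000), p = 1)
    ),
    square_monotone = scenario_config(
      name = "square_monotone", kind = "inversion", seed = seed,
      bank = list(components = list(default_component_spec(
        m = 5, ensemble = "gaussian", nonlinearity = "leaky_softplus",
        cond_cap = 1e3, id = "sq5"))),
      inversion = list(tol = 1e-12, max_iter = 50000),
      run = list(gains = c(1e2, 1e3, 1e4), p = c(0.4, -0.2, 0.7, 0.1, -0.5))
    ),
    blackbox = scenario_config(
      name = "blackbox", kind = "inversion", seed = seed,
      bank = list(components = list(default_component_spec(
        m = 5, kind = "blackbox", ensemble = "gaussian",
        nonlinearity = "leaky_softplus", cond_cap = 1e3, id = "bb5"))),
      inversion = list(tol = 1e-12, max_iter = 50000),
      run = list(gains = 1e3, p = c(0.4, -0.2, 0.7, 0.1, -0.5))
    ),
    delayed_loop = scenario_config(
      name = "delayed_loop", kind = "stability", seed = seed,
      bank = list(components = list(default_component_spec(
        m = 1, ensemble = "identity", scale = 2, id = "s2"))),
      inversion = list(mode = "dynamical", relax_step = 0.02, max_iter = 4000,
                       tol = 1e-8),
      run = list(gains = c(2, 10, 40), delays = c(0, 1, 2, 5, 10, 20, 40),
                 p = 1)
    ),
    two_bump_drive = scenario_config(
      name = "two_bump_drive", kind = "drive", seed = seed,
      world = list(dim_form = 2, dim_env = 0,
                   landscape = list(
                     list(center = c(0, 0), height = 0.4, width = 0.6),
                     list(center = c(1.2, 0), height = 1.2, width = 0.6)),
                   init_scale = 0, init_mean = c(0, 0), dt = 0.01),
      drive = list(sigma_max = 0.15,
                   modulation = list(family = "hill", x_half = 0.3,
                                     steepness = 6),
                   horizon_steps = 2500, estimate_noise_sd = 0, n_seeds = 20,
                   control = "matched_mean_sigma", window_frac = 0.2)
    ),
    dialogue_pair = scenario_config(
      name = "dialogue_pair", kind = "dialogue", seed = seed,
      bank = list(components = list(default_component_spec(
        m = 3, ensemble = "gaussian", nonlinearity = "leaky_softplus",
        cond_cap = 100, id = "d3"))),
      inversion = list(gain = 1e4, tol = 1e-12, max_iter = 50000),
      channel = list(noise_sd = 0, gain_loss = 1),
      run = list(n_turns = 12, u_init = c(0.5, -0.3, 0.2), delta = 0)
    ),
    internal_dialogue = scenario_config(
      name = "internal_dialogue", kind = "internal_dialogue", seed = seed,
      bank = list(components = list(default_component_spec(
        m = 3, ensemble = "spd", id = "spd3"))),
      loop = list(mode = "internal_dialogue"),
      inversion = list(gain = 30, tol = 1e-13, max_iter = 50000),
      run = list(n_cycles = 800, u_init = c(0.5, -0.2, 0.3))
    )
  )
}
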