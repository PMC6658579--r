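# Scenario configuration: a validated plain-list tree, serializable to JSON
# (canonical) or YAML (accepted). Components are stored as construction
# specs, not as built matrices, so files stay small and round-trip exactly.

scenario_kinds <- c("inversion", "stability", "loop", "internal_dialogue",
                    "dialogue", "drive")

# allowed keys per section; unknown keys are rejected with their full path
scenario_schema <- list(
  name = NA, kind = NA, seed = NA,
  world = list(dim_form = NA, dim_env = NA, landscape = NA, env_timescale = NA,
               env_sd = NA, env_gate = NA, obs_noise_sd = NA, dt = NA,
               init_scale = NA, init_mean = NA),
  bank = list(components = NA, weights = NA, output_map = NA),
  loop = list(cycle_period = NA, duty = NA, mode = NA, drift_within_cycle = NA),
  inversion = list(gain = NA, preconditioner = NA, mode = NA, damping = NA,
                   tol = NA, max_iter = NA, delay_steps = NA, relax_step = NA,
                   fd_step = NA, keep_trajectory = NA, divergence_factor = NA,
                   divergence_run = NA),
  channel = list(noise_sd = NA, gain_loss = NA),
  drive = list(sigma_max = NA, modulation = list(family = NA, x_half = NA,
                                                 steepness = NA),
               horizon_steps = NA, estimate_noise_sd = NA, n_seeds = NA,
               control = NA, window_frac = NA),
  run = list(gains = NA, delays = NA, p = NA, probe = NA, n_cycles = NA,
             u_init = NA, n_turns = NA, delta = NA, n_seeds = NA),
  outputs = list(directory = NA, formats = NA)
)

component_spec_keys <- c("id", "m", "n", "kind", "ensemble", "nonlinearity",
                         "drift_timescale", "drift_sd", "cond_cap", "scale",
                         "bias_sd")

check_keys <- function(x, schema, path) {
  extra <- setdiff(names(x), names(schema))
  if (length(extra) > 0) {
    stop("unknown configuration key: ",
         paste0(c(path, extra[1]), collapse = "."), call. = FALSE)
  }
  for (k in names(x)) {
    if (is.list(schema[[k]]) && !is.null(x[[k]])) {
      check_keys(x[[k]], schema[[k]],
                 if (is.null(path)) k else paste(path, k, sep = "."))
    }
  }
  invisible(TRUE)
}

check_positive <- function(x, key) {
  v <- x
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  if (!is.null(v) && (!is.numeric(v) || any(v <= 0))) {
    stop("configuration value must be positive: ", key, call. = FALSE)
  }
}

check_nonneg <- function(x, key) {
  v <- x
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  if (!is.null(v) && (!is.numeric(v) || any(v < 0))) {
    stop("configuration value must be non-negative: ", key, call. = FALSE)
  }
}

# deep-merge user values over defaults (NULL user keeps the default)
merge_defaults <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  for (k in names(defaults)) {
    user[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_defaults(user[[k]], defaults[[k]])
    } else if (is.null(user[[k]])) defaults[[k]] else user[[k]]
  }
  user
}

scenario_defaults <- function() {
  list(
    name = "scenario", kind = "inversion", seed = 1,
    world = list(dim_form = 2, dim_env = 0,
                 landscape = list(list(center = c(0, 0), height = 1, width = 1)),
                 env_timescale = 50, env_sd = 1, env_gate = 0, obs_noise_sd = 0,
                 dt = 0.01, init_scale = 1, init_mean = c(0, 0)),
    bank = list(components = list(default_component_spec()),
                weights = 1, output_map = "softplus"),
    loop = list(cycle_period = 0.1, duty = 0.5, mode = "external_input",
                drift_within_cycle = FALSE),
    inversion = list(gain = 100, preconditioner = "identity",
                     mode = "fixed_point", damping = 0.5, tol = 1e-10,
                     max_iter = 10000, delay_steps = 0, relax_step = 0.05,
                     fd_step = 1e-6, keep_trajectory = FALSE,
                     divergence_factor = 1e6, divergence_run = 50),
    channel = list(noise_sd = 0, gain_loss = 1),
    drive = list(sigma_max = 0.3,
                 modulation = list(family = "hill", x_half = 0.25, steepness = 4),
                 horizon_steps = 1500, estimate_noise_sd = 0, n_seeds = 20,
                 control = "matched_mean_sigma", window_frac = 0.2),
    run = list(gains = 100, p = 1, n_cycles = 10, u_init = 0.5,
               n_turns = 10, delta = 0, delays = 0),
    outputs = list(directory = NULL, formats = c("csv", "json"))
  )
}

default_component_spec <- function(m = 1, n = m, kind = "linear_monotone",
                                   ensemble = "gaussian",
                                   nonlinearity = "identity",
                                   drift_timescale = 100, drift_sd = 0,
                                   cond_cap = 1e4, scale = 1, bias_sd = 0,
                                   id = "c1") {
  list(id = id, m = m, n = n, kind = kind, ensemble = ensemble,
       nonlinearity = nonlinearity, drift_timescale = drift_timescale,
       drift_sd = drift_sd, cond_cap = cond_cap, scale = scale,
       bias_sd = bias_sd)
}

normalize_scenario <- function(x) {
  check_keys(x, scenario_schema, NULL)
  x <- merge_defaults(x, scenario_defaults())
  if (!x$kind %in% scenario_kinds) {
    stop("configuration value for 'kind' must be one of: ",
         paste(scenario_kinds, collapse = ", "), call. = FALSE)
  }
  check_positive(x, "inversion.gain")
  check_positive(x, "inversion.tol")
  check_positive(x, "inversion.relax_step")
  check_positive(x, "world.dt")
  check_positive(x, "world.env_timescale")
  check_positive(x, "loop.cycle_period")
  check_nonneg(x, "channel.noise_sd")
  check_positive(x, "channel.gain_loss")
  check_nonneg(x, "drive.sigma_max")
  check_nonneg(x, "drive.estimate_noise_sd")
  check_nonneg(x, "inversion.delay_steps")
  for (cs in x$bank$components) {
    extra <- setdiff(names(cs), component_spec_keys)
    if (length(extra) > 0) {
      stop("unknown configuration key: bank.components.", extra[1], call. = FALSE)
    }
  }
  # canonical numeric storage so serialization round-trips identically
  x$seed <- as.integer(x$seed)
  x$world$dim_form <- as.integer(x$world$dim_form)
  x$world$dim_env <- as.integer(x$world$dim_env)
  x$world$landscape <- lapply(x$world$landscape, function(b) {
    list(center = as.numeric(unlist(b$center)), height = as.numeric(b$height),
         width = as.numeric(b$width))
  })
  x$world$init_mean <- rep_len(as.numeric(x$world$init_mean), x$world$dim_form)
  for (k in c("env_timescale", "env_sd", "env_gate", "obs_noise_sd", "dt",
              "init_scale")) {
    x$world[[k]] <- as.numeric(x$world[[k]])
  }
  x$bank$components <- lapply(x$bank$components, function(cs) {
    cs <- merge_defaults(cs, default_component_spec())
    cs$m <- as.integer(cs$m)
    cs$n <- as.integer(cs$n)
    for (k in c("drift_timescale", "drift_sd", "cond_cap", "scale", "bias_sd")) {
      cs[[k]] <- as.numeric(cs[[k]])
    }
    cs[component_spec_keys]
  })
  x$bank$weights <- rep_len(as.numeric(x$bank$weights), length(x$bank$components))
  for (k in c("gain", "damping", "tol", "relax_step", "fd_step",
              "divergence_factor")) {
    x$inversion[[k]] <- as.numeric(x$inversion[[k]])
  }
  x$inversion$max_iter <- as.integer(x$inversion$max_iter)
  x$inversion$delay_steps <- as.integer(x$inversion$delay_steps)
  x$inversion$divergence_run <- as.integer(x$inversion$divergence_run)
  x$channel$noise_sd <- as.numeric(x$channel$noise_sd)
  x$channel$gain_loss <- as.numeric(x$channel$gain_loss)
  x$loop$cycle_period <- as.numeric(x$loop$cycle_period)
  x$loop$duty <- as.numeric(x$loop$duty)
  if (!is.null(x$run$probe)) x$run$probe <- as.numeric(x$run$probe)
  x$drive$horizon_steps <- as.integer(x$drive$horizon_steps)
  x$drive$n_seeds <- as.integer(x$drive$n_seeds)
  for (k in c("sigma_max", "estimate_noise_sd", "window_frac")) {
    x$drive[[k]] <- as.numeric(x$drive[[k]])
  }
  x$drive$modulation$x_half <- as.numeric(x$drive$modulation$x_half)
  x$drive$modulation$steepness <- as.numeric(x$drive$modulation$steepness)
  for (k in c("gains", "p", "u_init", "delta")) {
    if (!is.null(x$run[[k]])) x$run[[k]] <- as.numeric(x$run[[k]])
  }
  for (k in c("n_cycles", "n_turns", "n_seeds", "delays")) {
    if (!is.null(x$run[[k]])) x$run[[k]] <- as.integer(x$run[[k]])
  }
  # canonical outputs section (list() keeps an absent directory as NULL)
  x$outputs <- list(directory = x$outputs$directory,
                    formats = as.character(x$outputs$formats))
  structure(x, class = "scenario_config")
}

#' Create a scenario configuration
#'
#' A scenario bundles everything a run needs: the world, the estimator
#' bank (as construction specs), loop / inversion / channel / drive
#' settings, the run's own parameters, a seed, and output options.
#' Omitted values take documented defaults; unknown keys are rejected by
#' name. `kind` selects what [run_scenario()] does: `"inversion"`,
#' `"stability"`, `"loop"`, `"internal_dialogue"`, `"dialogue"` or
#' `"drive"`.
#'
#' @param ... Named top-level sections (`name`, `kind`, `seed`, `world`,
#'   `bank`, `loop`, `inversion`, `channel`, `drive`, `run`, `outputs`),
#'   each a named list.
#' @return A validated `scenario_config`.
#' @seealso [load_scenario()], [generate_fixture()], [run_scenario()]
#' @export
scenario_config <- function(...) normalize_scenario(list(...))

#' Load a scenario configuration file
#'
#' JSON is the canonical format; YAML is accepted (by `.yaml`/`.yml`
#' extension). The file is schema-validated, defaults are filled in, and
#' the effective configuration is returned (write it back next to the
#' outputs with [write_scenario()] to make the defaults auditable).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `scenario_config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  normalize_scenario(raw)
}

#' Write a scenario configuration as canonical JSON
#'
#' @param config A `scenario_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# build typed objects from the plain-list config ------------------------------

build_world <- function(cfg) {
  w <- cfg$world
  world_config(dim_form = w$dim_form, dim_env = w$dim_env,
               landscape = lapply(w$landscape, function(b) {
                 bump(b$center, b$height, b$width)
               }),
               env_timescale = w$env_timescale, env_sd = w$env_sd,
               env_gate = w$env_gate, obs_noise_sd = w$obs_noise_sd,
               dt = w$dt, init_scale = w$init_scale, init_mean = w$init_mean)
}

build_bank <- function(cfg) {
  comps <- lapply(cfg$bank$components, function(cs) {
    make_component(m = cs$m, n = cs$n, kind = cs$kind, ensemble = cs$ensemble,
                   nonlinearity = cs$nonlinearity,
                   drift_timescale = cs$drift_timescale, drift_sd = cs$drift_sd,
                   cond_cap = cs$cond_cap, scale = cs$scale, bias_sd = cs$bias_sd,
                   id = cs$id, seed = cfg$seed)
  })
  estimator_bank(comps, weights = cfg$bank$weights,
                 output_map = cfg$bank$output_map)
}

build_inversion <- function(cfg) {
  iv <- cfg$inversion
  inversion_config(gain = iv$gain, preconditioner = iv$preconditioner,
                   mode = iv$mode, damping = iv$damping, tol = iv$tol,
                   max_iter = iv$max_iter, delay_steps = iv$delay_steps,
                   relax_step = iv$relax_step, fd_step = iv$fd_step,
                   keep_trajectory = iv$keep_trajectory,
                   divergence_factor = iv$divergence_factor,
                   divergence_run = iv$divergence_run)
}

build_loop <- function(cfg) {
  lp <- cfg$loop
  loop_config(cycle_period = lp$cycle_period, duty = lp$duty, mode = lp$mode,
              inversion = build_inversion(cfg),
              drift_within_cycle = lp$drift_within_cycle)
}

build_drive <- function(cfg) {
  d <- cfg$drive
  drive_config(sigma_max = d$sigma_max, modulation = d$modulation,
               horizon_steps = d$horizon_steps,
               estimate_noise_sd = d$estimate_noise_sd, n_seeds = d$n_seeds,
               control = d$control, window_frac = d$window_frac)
}

build_channel <- function(cfg) {
  channel_config(noise_sd = cfg$channel$noise_sd,
                 gain_loss = cfg$channel$gain_loss)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config '%s'> kind = %s, seed = %d, %d component(s)\n",
              x$name, x$kind, x$seed, length(x$bank$components)))
  invisible(x)
}
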