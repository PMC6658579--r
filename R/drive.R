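#' Settings for the variance-modulated stochastic drive
#'
#' The drive implements the mechanism by which an internal fitness
#' estimate raises future fitness: the organism's form takes random,
#' undirected steps whose magnitude — never their direction — is a
#' decreasing function of the current estimate. Where the estimate is low
#' the form diffuses fast (desperate times), where it is high it barely
#' moves (never change a winning team), so forms drift away from
#' low-fitness regions and linger near peaks. The gradually accrued
#' fitness is summarized as "fitness-to-be", the trailing-window mean of
#' `f` at the end of the run.
#'
#' @param sigma_max Step sd at zero estimate (`sigma(0) = sigma_max`).
#' @param modulation List with `family` (`"hill"` or `"exponential"`),
#'   `x_half` (estimate at which the hill family halves sigma) and
#'   `steepness`.
#' @param horizon_steps Number of fast steps simulated.
#' @param estimate_noise_sd Sd of the noise separating the estimate from
#'   true fitness; `0` gives a perfect estimator, larger values degrade
#'   estimator quality in a controlled way.
#' @param n_seeds Default number of paired seeds for
#'   [compare_conditions()].
#' @param control `"matched_mean_sigma"` (control sigma fixed at the
#'   modulated run's time-average, the fair null in which only the
#'   estimate-dependence of sigma differs) or `"fixed_sigma"`.
#' @param window_frac Fraction of the horizon (from the end) averaged into
#'   fitness-to-be.
#' @return A `drive_config`.
#' @export
drive_config <- function(sigma_max = 0.3,
                         modulation = list(family = "hill", x_half = 0.25,
                                           steepness = 4),
                         horizon_steps = 1500, estimate_noise_sd = 0,
                         n_seeds = 20, control = c("matched_mean_sigma", "fixed_sigma"),
                         window_frac = 0.2) {
  control <- match.arg(control)
  stopifnot(sigma_max >= 0, horizon_steps >= 1, estimate_noise_sd >= 0,
            n_seeds >= 1, window_frac > 0, window_frac <= 1)
  stopifnot(is.list(modulation),
            modulation$family %in% c("hill", "exponential"),
            modulation$x_half > 0, modulation$steepness > 0)
  structure(list(sigma_max = sigma_max, modulation = modulation,
                 horizon_steps = as.integer(horizon_steps),
                 estimate_noise_sd = estimate_noise_sd,
                 n_seeds = as.integer(n_seeds), control = control,
                 window_frac = window_frac),
            class = "drive_config")
}

#' Step-size modulation: sigma as a decreasing function of the estimate
#'
#' Hill family: `sigma_max / (1 + (x / x_half)^steepness)` (halved exactly
#' at `x = x_half`). Exponential family:
#' `sigma_max * exp(-steepness * x / x_half)`. Both are strictly
#' decreasing in `x` with `sigma(0) = sigma_max`.
#'
#' @param x Non-negative fitness estimate (vectorized).
#' @param cfg A [drive_config()].
#' @return Step sd(s), same length as `x`.
#' @export
modulation_sigma <- function(x, cfg) {
  stopifnot(inherits(cfg, "drive_config"), all(x >= 0))
  m <- cfg$modulation
  switch(m$family,
    hill = cfg$sigma_max / (1 + (x / m$x_half)^m$steepness),
    exponential = cfg$sigma_max * exp(-m$steepness * x / m$x_half)
  )
}

#' One undirected random step of the organism's form
#'
#' `theta' = theta + sigma * xi` with `xi` i.i.d. standard normal per
#' coordinate: the direction is uniformly random, only the variance is
#' modulated. Consumes the current RNG state.
#'
#' @param theta Current form vector.
#' @param sigma Step sd (scalar, >= 0).
#' @return The stepped form vector.
#' @export
step_form <- function(theta, sigma) {
  stopifnot(sigma >= 0)
  theta + sigma * stats::rnorm(length(theta))
}

#' Simulate the stochastic drive
#'
#' Per step: evaluate fitness `f` at the current form, form the estimate
#' `x = max(0, f + noise)`, set the step sd by [modulation_sigma()], and
#' step the form. The estimate is true fitness plus controllable noise by
#' default, so estimator quality is a clean dial; with `use_bank` the
#' estimate instead runs the full sense-then-estimate chain of a bank.
#'
#' @param world_cfg A [world_config()] (its `landscape` and `init_*`
#'   fields position the starting form on the landscape).
#' @param cfg A [drive_config()].
#' @param seed Integer seed (streams `"world"` for the start, `"drive"`
#'   for the steps).
#' @param sigma_fixed If non-`NULL`, a constant sigma overriding the
#'   modulation — the control condition. The same number of random draws
#'   is consumed per step either way, so runs pair exactly by seed.
#' @param use_bank Optional [estimator_bank()]; when given, `x` comes from
#'   `estimate_fitness(bank, sense(state))` instead of `f` plus noise.
#' @return A `drive_trace` tibble with columns `t`, `theta` (list),
#'   `f`, `x`, `sigma`; attributes `f_plus` (trailing-window mean of `f`),
#'   `mean_sigma` (time-average sigma) and `window_steps`.
#' @export
run_drive <- function(world_cfg, cfg, seed = 1, sigma_fixed = NULL,
                      use_bank = NULL) {
  stopifnot(inherits(world_cfg, "world_config"), inherits(cfg, "drive_config"))
  state <- init_world(world_cfg, seed)
  set.seed(stream_seed(seed, "drive"))
  n <- cfg$horizon_steps
  f_v <- x_v <- s_v <- numeric(n)
  th <- vector("list", n)
  for (i in seq_len(n)) {
    f <- evaluate_fitness(state, world_cfg)$f
    # always one draw per step so modulated/control runs pair exactly by seed
    noise <- stats::rnorm(1) * cfg$estimate_noise_sd
    x <- if (is.null(use_bank)) {
      max(0, f + noise)
    } else {
      estimate_fitness(use_bank, sense(state, world_cfg))
    }
    sg <- if (is.null(sigma_fixed)) modulation_sigma(x, cfg) else sigma_fixed
    th[[i]] <- state$theta
    f_v[i] <- f
    x_v[i] <- x
    s_v[i] <- sg
    state$theta <- step_form(state$theta, sg)
    state$t <- state$t + world_cfg$dt
  }
  out <- tibble::tibble(t = (seq_len(n) - 1) * world_cfg$dt,
                        theta = th, f = f_v, x = x_v, sigma = s_v)
  win <- max(1L, ceiling(cfg$window_frac * n))
  attr(out, "f_plus") <- mean(f_v[(n - win + 1L):n])
  attr(out, "mean_sigma") <- mean(s_v)
  attr(out, "window_steps") <- win
  class(out) <- c("drive_trace", class(out))
  out
}

#' Fitness-to-be of a drive trace
#'
#' @param trace A `drive_trace`.
#' @return The trailing-window mean fitness.
#' @export
fitness_to_be <- function(trace) {
  stopifnot(inherits(trace, "drive_trace"))
  attr(trace, "f_plus")
}

#' Does modulating the step size by the estimate raise fitness-to-be?
#'
#' Runs the modulated drive and a matched control for each of `n_seeds`
#' paired seeds. The control takes constant-sd steps equal to the
#' modulated run's own time-average sigma (same seed, same draws), so the
#' mean step size is equalized and only the estimate-dependence differs.
#' Significance of "modulated beats control" is assessed by a one-sided
#' paired sign-flip permutation test on the per-seed fitness-to-be
#' differences.
#'
#' @param world_cfg A [world_config()].
#' @param cfg A [drive_config()].
#' @param n_seeds Number of paired seeds (default `cfg$n_seeds`).
#' @param seed Root seed; per-run seeds are `seed * 1000 + i`.
#' @param n_perm Number of sign-flip permutations.
#' @return A `drive_comparison` list: tibble `per_seed` (`seed`,
#'   `f_plus_modulated`, `f_plus_control`, `diff`, `mean_sigma`),
#'   `mean_diff`, `p_value`, `n_seeds`, `n_perm`.
#' @export
compare_conditions <- function(world_cfg, cfg, n_seeds = cfg$n_seeds,
                               seed = 1, n_perm = 10000) {
  stopifnot(n_seeds >= 2)
  per <- purrr::map(seq_len(n_seeds), function(i) {
    si <- (seed * 1000 + i) %% 2147483647
    mod <- run_drive(world_cfg, cfg, seed = si)
    ms <- attr(mod, "mean_sigma")
    sig_ctl <- if (cfg$control == "matched_mean_sigma") ms else cfg$sigma_max
    ctl <- run_drive(world_cfg, cfg, seed = si, sigma_fixed = sig_ctl)
    tibble::tibble(seed = si, f_plus_modulated = fitness_to_be(mod),
                   f_plus_control = fitness_to_be(ctl), mean_sigma = ms)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(diff = .data$f_plus_modulated - .data$f_plus_control)
  mean_diff <- mean(per$diff)
  p <- sign_flip_p(per$diff, n_perm = n_perm, seed = stream_seed(seed, "perm"))
  structure(list(per_seed = per, mean_diff = mean_diff, p_value = p,
                 n_seeds = n_seeds, n_perm = n_perm),
            class = "drive_comparison")
}

# one-sided paired sign-flip permutation p-value for mean(d) > 0
sign_flip_p <- function(d, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- mean(d)
  flips <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                  nrow = n_perm)
  perm <- drop(flips %*% d) / length(d)
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

#' Sweep estimator quality and measure fitness-to-be
#'
#' Degrades the estimator by increasing `estimate_noise_sd` and records
#' fitness-to-be per seed per level: the testable core of the claim that
#' a better estimator yields higher eventual fitness.
#'
#' @param world_cfg A [world_config()].
#' @param cfg A [drive_config()] (its own `estimate_noise_sd` is ignored).
#' @param noise_levels Numeric vector of estimate noise sds.
#' @param n_seeds Seeds per level.
#' @param seed Root seed.
#' @return A tibble (`noise_sd`, `seed`, `f_plus`).
#' @export
sweep_estimate_noise <- function(world_cfg, cfg,
                                 noise_levels = c(0, 0.5, 1, 2, 4),
                                 n_seeds = 20, seed = 1) {
  tidyr::expand_grid(noise_sd = noise_levels, i = seq_len(n_seeds)) |>
    purrr::pmap(function(noise_sd, i) {
      cfg_i <- cfg
      cfg_i$estimate_noise_sd <- noise_sd
      si <- (seed * 1000 + i) %% 2147483647
      tibble::tibble(noise_sd = noise_sd, seed = si,
                     f_plus = fitness_to_be(run_drive(world_cfg, cfg_i, seed = si)))
    }) |> dplyr::bind_rows()
}

#' Permutation test for a monotone trend
#'
#' Spearman rank correlation between `x` and `y` with a label-shuffling
#' permutation p-value; `alternative = "less"` tests for a decreasing
#' trend.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_perm Number of permutations.
#' @param alternative `"less"` or `"greater"`.
#' @param seed Seed for the permutation draws.
#' @return List with `statistic` (Spearman rho) and `p_value`.
#' @export
trend_test <- function(x, y, n_perm = 2000, alternative = c("less", "greater"),
                       seed = 1) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 3)
  set.seed(seed)
  obs <- stats::cor(x, y, method = "spearman")
  perm <- replicate(n_perm, stats::cor(x, sample(y), method = "spearman"))
  p <- if (alternative == "less") {
    (1 + sum(perm <= obs)) / (n_perm + 1)
  } else {
    (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  list(statistic = obs, p_value = p)
}
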