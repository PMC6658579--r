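#' Run a scenario end to end
#'
#' Builds the configured objects, dispatches on the scenario `kind`, and
#' returns a `run_summary` carrying the key metrics plus every trace as a
#' tidy tibble. If `config$outputs$directory` is set, all traces, the
#' summary and the effective configuration are written there (see
#' [write_outputs()]). Fully reproducible: the seed determines every
#' number in the output.
#'
#' @param config A `scenario_config` (e.g. from [generate_fixture()] or
#'   [load_scenario()]).
#' @return A `run_summary` list: `scenario`, `kind`, `seed`,
#'   `config_hash`, `metrics` (named list of scalars), `traces` (named
#'   list of tibbles), `wall_time` (seconds).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dir <- config$outputs$directory
  if (!is.null(dir)) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(dir, mode = 2) != 0) {
      stop("output directory is not writable: ", dir, call. = FALSE)
    }
  }
  t0 <- proc.time()[["elapsed"]]
  res <- switch(config$kind,
    inversion = scenario_inversion(config),
    stability = scenario_stability(config),
    loop = scenario_loop(config),
    internal_dialogue = scenario_internal_dialogue(config),
    dialogue = scenario_dialogue(config),
    drive = scenario_drive(config)
  )
  summary <- structure(
    list(scenario = config$name, kind = config$kind, seed = config$seed,
         config_hash = rlang::hash(unclass(config)),
         metrics = res$metrics, traces = res$traces,
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "run_summary"
  )
  if (!is.null(dir)) write_outputs(res$traces, summary, config)
  summary
}

scenario_inversion <- function(config) {
  comp <- build_bank(config)$components[[1]]
  S <- as_operator(comp)
  p <- config$run$p
  base <- build_inversion(config)
  rows <- purrr::map(config$run$gains, function(g) {
    cfg <- base
    cfg$gain <- g
    r <- invert_operator(S, p, cfg)
    rt <- sqrt(sum((S$forward(r$q) - p)^2)) / max(sqrt(sum(p^2)), .Machine$double.eps)
    oracle_err <- NA_real_
    if (comp$kind == "linear_monotone" && comp$m == comp$n) {
      u_star <- analytic_linear_oracle(comp$A, comp$b, comp$nonlinearity, p)
      oracle_err <- sqrt(sum((r$q - u_star)^2)) /
        max(sqrt(sum(u_star^2)), .Machine$double.eps)
    }
    tibble::tibble(gain = g, q = list(r$q), residual = r$residual,
                   roundtrip_error = rt, oracle_error = oracle_err,
                   iterations = r$iterations, converged = r$converged,
                   diverged = r$diverged)
  })
  trace <- dplyr::bind_rows(rows)
  list(traces = list(inversion = trace),
       metrics = list(max_roundtrip_error = max(trace$roundtrip_error),
                      min_roundtrip_error = min(trace$roundtrip_error),
                      all_converged = all(trace$converged)))
}

scenario_stability <- function(config) {
  comp <- build_bank(config)$components[[1]]
  cfg <- build_inversion(config)
  cfg$mode <- "dynamical"
  sm <- stability_map(as_operator(comp), config$run$gains, config$run$delays,
                      cfg, probe = config$run$p)
  list(traces = list(stability = sm),
       metrics = list(n_diverged = sum(sm$diverged),
                      n_converged = sum(sm$converged),
                      monotone_violations = attr(sm, "monotone_violations")))
}

scenario_loop <- function(config) {
  comp <- build_bank(config)$components[[1]]
  lp <- build_loop(config)
  u <- rep_len(config$run$u_init, comp$m)
  trace <- run_external(comp, u, config$run$n_cycles, lp)
  list(traces = list(loop = trace),
       metrics = list(final_roundtrip_error = utils::tail(trace$roundtrip_error, 1),
                      mean_roundtrip_error = mean(trace$roundtrip_error),
                      n_diverged = sum(trace$diverged)))
}

scenario_internal_dialogue <- function(config) {
  comp <- build_bank(config)$components[[1]]
  lp <- build_loop(config)
  lp$mode <- "internal_dialogue"
  u0 <- rep_len(config$run$u_init, comp$m)
  trace <- run_internal_dialogue(comp, u0, config$run$n_cycles, lp)
  deltas <- trace$delta_u[!is.na(trace$delta_u)]
  list(traces = list(internal_dialogue = trace),
       metrics = list(final_delta_u = utils::tail(deltas, 1),
                      n_diverged = sum(trace$diverged)))
}

scenario_dialogue <- function(config) {
  bank <- build_bank(config)
  lp <- build_loop(config)
  sender <- agent(bank, lp, role = "sender")
  set.seed(stream_seed(config$seed, "perturb"))
  receiver <- perturb_agent(agent(bank, lp, role = "receiver"),
                            config$run$delta %||% 0)
  set.seed(stream_seed(config$seed, "channel"))
  comp <- agent_component(sender)
  trace <- run_dialogue(sender, receiver, build_channel(config),
                        n_turns = config$run$n_turns,
                        u_init = rep_len(config$run$u_init, comp$m))
  list(traces = list(dialogue = trace),
       metrics = list(max_reconstruction_error = max(trace$reconstruction_error),
                      median_reconstruction_error = stats::median(trace$reconstruction_error),
                      n_diverged = sum(trace$diverged)))
}

scenario_drive <- function(config) {
  wc <- build_world(config)
  dc <- build_drive(config)
  cmp <- compare_conditions(wc, dc, n_seeds = dc$n_seeds, seed = config$seed)
  list(traces = list(drive_comparison = cmp$per_seed),
       metrics = list(mean_f_plus_modulated = mean(cmp$per_seed$f_plus_modulated),
                      mean_f_plus_control = mean(cmp$per_seed$f_plus_control),
                      mean_paired_diff = cmp$mean_diff,
                      p_value = cmp$p_value))
}

# expand list-columns of numeric vectors into name_1..name_k columns
flatten_trace <- function(tr) {
  tr <- tibble::as_tibble(tr)
  listcols <- names(tr)[vapply(tr, is.list, logical(1))]
  for (nm in listcols) {
    lens <- lengths(tr[[nm]])
    k <- max(lens, 1L)
    mat <- t(vapply(tr[[nm]], function(v) {
      c(as.numeric(v), rep(NA_real_, k - length(v)))
    }, numeric(k)))
    mat <- matrix(mat, ncol = k,
                  dimnames = list(NULL, paste0(nm, "_", seq_len(k))))
    tr[[nm]] <- NULL
    tr <- dplyr::bind_cols(tr, tibble::as_tibble(mat))
  }
  tr
}

#' Write a run's traces, summary and effective configuration
#'
#' One CSV per trace (header row, UTF-8, `.` decimal; vector-valued
#' columns expanded to `name_1 .. name_k`), a JSON summary, and a JSON
#' copy of the effective configuration. Filenames embed the scenario name
#' and seed.
#'
#' @param traces Named list of tibbles.
#' @param summary A `run_summary`.
#' @param config The `scenario_config` that produced them.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(traces, summary, config) {
  stopifnot(inherits(config, "scenario_config"))
  dir <- config$outputs$directory
  if (is.null(dir)) stop("config$outputs$directory is not set", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_seed%d", config$name, config$seed))
  files <- character(0)
  if ("csv" %in% config$outputs$formats) {
    for (nm in names(traces)) {
      f <- paste0(stem, "_", nm, ".csv")
      readr::write_csv(flatten_trace(traces[[nm]]), f)
      files <- c(files, f)
    }
  }
  if ("json" %in% config$outputs$formats) {
    f <- paste0(stem, "_summary.json")
    jsonlite::write_json(
      list(scenario = summary$scenario, kind = summary$kind,
           seed = summary$seed, config_hash = summary$config_hash,
           metrics = summary$metrics, wall_time = summary$wall_time),
      f, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    files <- c(files, f)
    fc <- paste0(stem, "_config.json")
    write_scenario(config, fc)
    files <- c(files, fc)
  }
  invisible(files)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary '%s'> kind = %s, seed = %d (%.2fs)\n",
              x$scenario, x$kind, x$seed, x$wall_time))
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.numeric(v)) format(v, digits = 6) else as.character(v)))
  }
  invisible(x)
}
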