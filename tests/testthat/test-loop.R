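high_gain_loop <- function(...) {
  loop_config(inversion = inversion_config(gain = 1e4, tol = 1e-12,
                                           max_iter = 5e4), ...)
}

test_that("stage 1 writes only the x buffer, stage 2 only the u buffer", {
  comp <- identity_comp(2)
  buf <- loop_buffers(2)
  buf1 <- run_stage1(comp, c(1, 2), buf, time = 0.05)
  expect_equal(buf1$x_buf, c(1, 2))
  expect_identical(buf1$u_buf, buf$u_buf) # untouched

  # repeated stage 1 with the same input overwrites identically
  expect_equal(run_stage1(comp, c(1, 2), buf1)$x_buf, buf1$x_buf)

  st2 <- run_stage2(comp, buf1, inversion_config(gain = 1e4, tol = 1e-12))
  expect_equal(st2$buffers$x_buf, buf1$x_buf) # untouched
  expect_equal(st2$buffers$u_buf, c(1, 2), tolerance = 1e-3)

  expect_error(run_stage2(comp, buf, inversion_config()), "stage 1")
})

test_that("stage 2 reproduces the scalar feedback closed form", {
  comp <- make_component(m = 1, ensemble = "identity", scale = 2, seed = 1)
  buf <- run_stage1(comp, 0.5, loop_buffers(1))
  expect_equal(buf$x_buf, 1)
  st2 <- run_stage2(comp, buf, inversion_config(gain = 100, tol = 1e-12))
  expect_equal(st2$buffers$u_buf, 100 / 201, tolerance = 1e-8)
})

test_that("a diverged inversion holds the previous u buffer", {
  comp <- identity_comp(1)
  buf <- run_stage1(comp, 0.8, loop_buffers(1))
  buf$u_buf <- 0.123 # pretend a previous cycle latched this
  # dynamical mode with heavy delay genuinely diverges
  bad <- inversion_config(gain = 40, mode = "dynamical", relax_step = 0.9,
                          delay_steps = 30, max_iter = 500)
  st2 <- run_stage2(comp, buf, bad)
  expect_true(st2$result$diverged)
  expect_equal(st2$buffers$u_buf, 0.123)
})

test_that("the external loop keeps buffer discipline and is stationary without drift", {
  comp <- monotone_comp(3, seed = 5)
  tr <- run_external(comp, c(0.5, -0.3, 0.2), 6, high_gain_loop())
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$same_instance))
  expect_true(all(tr$converged))
  expect_lt(max(tr$roundtrip_error), 1e-3)
  # with drift_sd = 0 every cycle is identical after the first
  for (col in c("x", "u_hat")) {
    first <- tr[[col]][[1]]
    expect_true(all(vapply(tr[[col]], identical, logical(1), first)))
  }
  expect_equal(nrow(run_external(comp, c(0, 0, 0), 0, high_gain_loop())), 0)
})

test_that("round-trip error grows monotonically with parameter drift", {
  drift_levels <- c(0, 0.02, 0.06, 0.2, 0.6)
  med_err <- vapply(drift_levels, function(ds) {
    errs <- vapply(1:10, function(s) {
      comp <- make_component(m = 3, nonlinearity = "leaky_softplus",
                             cond_cap = 100, seed = s, drift_sd = ds,
                             drift_timescale = 1)
      set.seed(1000 + s)
      tr <- run_external(comp, c(0.5, -0.3, 0.2), 15,
                         loop_config(drift_within_cycle = TRUE,
                                     inversion = inversion_config(gain = 1e4,
                                                                  tol = 1e-11,
                                                                  max_iter = 3e4)))
      stats::median(tr$roundtrip_error)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
  expect_lt(med_err[1], 1e-3)
})

test_that("internal dialogue contracts to a fixed point when stationary", {
  comp <- make_component(m = 3, ensemble = "spd", seed = 2)
  cfg <- loop_config(mode = "internal_dialogue",
                     inversion = inversion_config(gain = 30, tol = 1e-13,
                                                  max_iter = 5e4))
  tr <- run_internal_dialogue(comp, c(0.5, -0.2, 0.3), 120, cfg)
  d <- tr$delta_u[-1]
  expect_true(all(diff(d) <= 1e-12))
  expect_lt(d[length(d)] / d[1], 0.1)

  # identity component with high gain: fixed at the input from cycle 1
  id <- identity_comp(1)
  tr2 <- run_internal_dialogue(id, 0.5, 4, high_gain_loop(mode = "internal_dialogue"))
  expect_equal(unlist(tr2$u_hat), rep(0.5, 4), tolerance = 1e-3)
})

test_that("drift makes the internal dialogue wander, with variance scaling as drift_sd^2", {
  # one fixed component, several realizations of its drift: the spread of
  # u_hat across realizations is purely drift-induced
  u_at <- function(ds, stream) {
    comp <- make_component(m = 2, ensemble = "spd", seed = 7, drift_sd = ds,
                           drift_timescale = 0.5)
    set.seed(stream)
    cfg <- loop_config(mode = "internal_dialogue",
                       inversion = inversion_config(gain = 50, tol = 1e-12,
                                                    max_iter = 3e4))
    tr <- run_internal_dialogue(comp, c(0.4, -0.1), 40, cfg)
    unlist(tr$u_hat[[40]])
  }
  levels <- c(1e-3, 2e-3, 4e-3)
  v <- vapply(levels, function(ds) {
    U <- t(vapply(1:8, function(st) u_at(ds, 100 + st), numeric(2)))
    sum(apply(U, 2, stats::var))
  }, numeric(1))
  expect_true(all(v > 0))
  fit <- stats::lm(log(v) ~ log(levels))
  expect_equal(unname(stats::coef(fit)[2]), 2, tolerance = 0.25)

  # and a stationary component does not wander at all
  u0 <- u_at(0, 1)
  expect_identical(u_at(0, 2), u0)
})
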