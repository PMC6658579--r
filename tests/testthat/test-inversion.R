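test_that("fixed-point inversion reproduces the scalar closed forms", {
  # S = identity: equilibrium q = g p / (1 + g)
  r <- invert_fixed_point(scalar_op(1), 3, inversion_config(gain = 100, tol = 1e-12))
  expect_equal(r$q, 300 / 101, tolerance = 1e-9)
  expect_equal(r$residual, 3 / 101, tolerance = 1e-6)
  expect_true(r$converged)

  # S = 2q: q = g p / (1 + 2 g), off the true inverse 0.5 by 1/402
  r2 <- invert_fixed_point(scalar_op(2), 1, inversion_config(gain = 100, tol = 1e-12))
  expect_equal(r2$q, 100 / 201, tolerance = 1e-9)
  expect_equal(abs(r2$q - 0.5), 1 / 402, tolerance = 1e-6)

  # S = 0: no feedback signal, q settles at g B p
  r3 <- invert_fixed_point(scalar_op(0), 0.7,
                           inversion_config(gain = 5, damping = 0.2, tol = 1e-12))
  expect_equal(r3$q, 3.5, tolerance = 1e-8)
  expect_true(r3$converged)
})

test_that("the error against the true inverse scales as 1/g", {
  s <- 2
  p <- 1
  gains <- c(10, 100, 1000)
  errs <- vapply(gains, function(g) {
    abs(invert_fixed_point(scalar_op(s), p,
                           inversion_config(gain = g, tol = 1e-13,
                                            max_iter = 1e5))$q - p / s)
  }, numeric(1))
  expect_equal(errs, p / (s * (1 + gains * s)), tolerance = 1e-6)
})

test_that("analytic oracle inverts the linear-monotone family exactly", {
  expect_equal(analytic_linear_oracle(diag(3), rep(0, 3), "identity",
                                      c(1, 2, 3)),
               c(1, 2, 3))
  expect_equal(analytic_linear_oracle(matrix(2, 1, 1), 0, "identity", 1), 0.5)

  set.seed(10)
  for (i in 1:5) {
    comp <- monotone_comp(5, seed = i, bias_sd = 0.3)
    p <- rnorm(5)
    u <- analytic_linear_oracle(comp$A, comp$b, comp$nonlinearity, p)
    expect_equal(apply_component(comp, u), p, tolerance = 1e-10)
  }
  expect_error(analytic_linear_oracle(matrix(0, 2, 2), c(0, 0), "identity",
                                      c(1, 1)), "singular")
})

test_that("feedback inversion agrees with the oracle and improves with gain", {
  set.seed(1)
  worst_ratio <- 0
  for (i in 1:12) {
    n <- sample(2:8, 1)
    comp <- monotone_comp(n, seed = 100 + i, bias_sd = 0.2)
    p <- rnorm(n) / 2
    u_star <- analytic_linear_oracle(comp$A, comp$b, comp$nonlinearity, p)
    err <- vapply(c(100, 1000), function(g) {
      r <- invert_fixed_point(as_operator(comp), p,
                              inversion_config(gain = g, tol = 1e-13,
                                               max_iter = 5e4))
      expect_true(r$converged)
      sqrt(sum((r$q - u_star)^2)) / sqrt(sum(u_star^2))
    }, numeric(1))
    expect_lt(err[1], 1)        # bounded by C/g with a loose constant
    expect_lt(err[2], err[1] / 5) # at least 5x shrink for a 10x gain
    worst_ratio <- max(worst_ratio, err[2] / err[1])
  }
  expect_lt(worst_ratio, 0.2)
})

test_that("round-trip fidelity improves monotonically with gain", {
  comp <- monotone_comp(5, seed = 17)
  p <- c(0.4, -0.2, 0.7, 0.1, -0.5)
  rt <- vapply(c(1e2, 1e3, 1e4), function(g) {
    r <- invert_fixed_point(as_operator(comp), p,
                            inversion_config(gain = g, tol = 1e-13,
                                             max_iter = 5e4))
    sqrt(sum((apply_component(comp, r$q) - p)^2)) / sqrt(sum(p^2))
  }, numeric(1))
  expect_true(all(diff(rt) < 0))
  expect_lt(rt[3], 1e-3)
})

test_that("blackbox components are inverted through feedback alone", {
  bb <- make_component(m = 5, kind = "blackbox", nonlinearity = "leaky_softplus",
                       cond_cap = 1e3, seed = 42, id = "bb")
  p <- c(0.4, -0.2, 0.7, 0.1, -0.5)
  r <- invert_fixed_point(as_operator(bb), p,
                          inversion_config(gain = 1e3, tol = 1e-13, max_iter = 5e4))
  expect_true(r$converged)
  expect_lt(sqrt(sum((apply_component(bb, r$q) - p)^2)) / sqrt(sum(p^2)), 1e-2)
})

test_that("the transpose-linearization preconditioner handles non-square maps", {
  # overdetermined: m_out > m_in, minimum-distance solution
  S <- as_operator(function(q) c(q, 2 * q), m_in = 1, m_out = 2)
  r <- invert_fixed_point(S, c(1, 2),
                          inversion_config(gain = 1e3,
                                           preconditioner = "transpose_linearization",
                                           tol = 1e-12, max_iter = 2e4))
  expect_equal(r$q, 1, tolerance = 1e-2)
  expect_false(r$non_unique)

  # underdetermined: m_out < m_in flags non-uniqueness
  S2 <- as_operator(function(q) sum(q), m_in = 2, m_out = 1)
  r2 <- invert_fixed_point(S2, 1,
                           inversion_config(gain = 1e3,
                                            preconditioner = "transpose_linearization",
                                            tol = 1e-12, max_iter = 2e4))
  expect_true(r2$non_unique)
  expect_equal(sum(r2$q), 1, tolerance = 1e-2)

  expect_error(invert_fixed_point(S, c(1, 2), inversion_config(gain = 10)),
               "preconditioner")
})

test_that("dynamical mode matches the fixed point without delay", {
  cfg <- inversion_config(gain = 100, mode = "dynamical", relax_step = 0.002,
                          tol = 1e-11, max_iter = 5e4)
  r <- invert_dynamical(scalar_op(2), 1, cfg)
  expect_true(r$converged)
  expect_equal(r$q, 100 / 201, tolerance = 1e-6)

  # zero input relaxes to zero
  r0 <- invert_dynamical(scalar_op(2), 0, cfg)
  expect_equal(r0$q, 0, tolerance = 1e-9)
})

test_that("delay destabilizes the dynamical loop past a boundary", {
  cfg <- inversion_config(gain = 40, mode = "dynamical", relax_step = 0.02,
                          tol = 1e-8, max_iter = 4000)
  r0 <- invert_dynamical(scalar_op(2), 1, cfg)
  expect_true(r0$converged)

  cfg$delay_steps <- 20L
  rd <- invert_dynamical(scalar_op(2), 1, cfg)
  expect_true(rd$diverged)
  expect_false(rd$converged)
  expect_true(all(is.finite(rd$q)))
})

test_that("stability_map tabulates the boundary deterministically", {
  cfg <- inversion_config(mode = "dynamical", relax_step = 0.02, tol = 1e-8,
                          max_iter = 3000)
  sm <- stability_map(scalar_op(2), gains = c(2, 40), delays = c(0, 40), cfg)
  expect_equal(nrow(sm), 4)
  expect_true(all(sm$converged[sm$delay == 0]))
  expect_true(all(sm$diverged[sm$delay == 40]))
  expect_equal(attr(sm, "monotone_violations"), 0)

  # tiny gain never diverges but leaves a large residual
  sm2 <- stability_map(scalar_op(2), gains = 0.001, delays = c(0, 20, 80), cfg)
  expect_false(any(sm2$diverged))
  expect_true(all(sm2$residual > 0.9))

  # duplicated grid point gives identical outcomes
  sm3 <- stability_map(scalar_op(2), gains = c(2, 2), delays = 5, cfg)
  expect_equal(sm3[1, -1], sm3[2, -1])
})
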