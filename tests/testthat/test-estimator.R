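test_that("component construction: identity, determinism, condition cap", {
  comp <- identity_comp(m = 1)
  expect_equal(comp$A, matrix(1, 1, 1))
  expect_equal(comp$b, 0)

  expect_identical(monotone_comp(5, seed = 3), monotone_comp(5, seed = 3))
  expect_false(identical(monotone_comp(5, seed = 3)$A,
                         monotone_comp(5, seed = 4)$A))

  for (s in 1:20) {
    comp <- make_component(m = 6, cond_cap = 50, seed = s)
    expect_lte(kappa(comp$A, exact = TRUE), 50 * (1 + 1e-10))
  }
})

test_that("apply_component evaluates phi(A u + b) and checks dimensions", {
  comp <- identity_comp(m = 2)
  expect_equal(apply_component(comp, c(0.3, -1.2)), c(0.3, -1.2))

  comp2 <- make_component(m = 1, ensemble = "identity", scale = 2, seed = 1)
  expect_equal(apply_component(comp2, 1), 2)

  expect_error(apply_component(comp, c(1, 2, 3)), "dim")
})

test_that("the leaky-softplus nonlinearity is increasing, bijective, invertible", {
  z <- seq(-40, 40, length.out = 400)
  y <- fitloop:::phi_eval("leaky_softplus", z)
  expect_true(all(diff(y) > 0))
  expect_equal(fitloop:::phi_inverse("leaky_softplus", y), z, tolerance = 1e-9)
})

test_that("a blackbox component matches the reference map it wraps", {
  ref <- make_component(m = 4, nonlinearity = "leaky_softplus", seed = 9,
                        bias_sd = 0.2, id = "w")
  bb <- make_component(m = 4, kind = "blackbox", nonlinearity = "leaky_softplus",
                       seed = 9, bias_sd = 0.2, id = "w")
  set.seed(1)
  for (i in 1:100) {
    u <- rnorm(4)
    expect_equal(apply_component(bb, u), apply_component(ref, u))
  }
})

test_that("aggregation is a weighted mean-pool through a non-negative squash", {
  comps <- list(identity_comp(2), identity_comp(2))
  bank <- estimator_bank(comps, weights = c(1, 1), output_map = "relu")
  # zero input through relu gives 0; softplus gives its documented constant
  expect_equal(aggregate_estimate(bank, list(c(0, 0), c(0, 0))), 0)
  bank_sp <- estimator_bank(comps, weights = c(1, 1), output_map = "softplus")
  expect_equal(aggregate_estimate(bank_sp, list(c(0, 0), c(0, 0))), log(2))

  # single component, weight 1, relu: pass-through of the mean
  b1 <- estimator_bank(list(identity_comp(2)), output_map = "relu")
  expect_equal(aggregate_estimate(b1, list(c(0.7, 0.7))), 0.7)

  # doubling the weights doubles the pre-squash sum (linear regime of relu)
  b2 <- estimator_bank(comps, weights = c(2, 2), output_map = "relu")
  expect_equal(aggregate_estimate(b2, list(c(0.5, 0.7), c(0.2, 0.4))),
               2 * aggregate_estimate(bank, list(c(0.5, 0.7), c(0.2, 0.4))))

  expect_error(aggregate_estimate(bank, list(c(0, 0))), "length")
})

test_that("the scalar estimate is non-negative for arbitrary inputs", {
  bank <- estimator_bank(list(monotone_comp(3, seed = 2),
                              monotone_comp(2, seed = 3)),
                         weights = c(1.5, -2))
  set.seed(8)
  for (i in 1:50) {
    x <- estimate_fitness(bank, rnorm(5, sd = 5))
    expect_true(is.finite(x) && x >= 0)
  }
})

test_that("linear_monotone components are injective on random inputs", {
  comp <- monotone_comp(4, seed = 6)
  set.seed(2)
  U <- matrix(rnorm(4 * 40), ncol = 4)
  Y <- t(apply(U, 1, function(u) apply_component(comp, u)))
  d <- as.matrix(dist(Y))
  expect_true(all(d[upper.tri(d)] > 1e-8))
})

test_that("parameter drift is mean-reverting, capped, and reproducible", {
  comp <- monotone_comp(4, seed = 1)
  expect_identical(drift_parameters(comp, 0.1), comp) # drift_sd = 0 freezes

  compd <- make_component(m = 4, nonlinearity = "leaky_softplus", seed = 1,
                          drift_sd = 0.05, drift_timescale = 10, cond_cap = 30)
  set.seed(3)
  d1 <- drift_parameters(compd, 0.1)
  set.seed(3)
  d2 <- drift_parameters(compd, 0.1)
  expect_identical(d1, d2)
  expect_false(identical(d1$A, compd$A))

  # condition cap still holds after many drift steps
  set.seed(4)
  cc <- compd
  for (i in 1:200) cc <- drift_parameters(cc, 0.5)
  expect_lte(kappa(cc$A, exact = TRUE), 30 * (1 + 1e-10))

  # stationarity of the bank with drift_sd = 0
  u <- c(1, -1, 0.5, 2)
  expect_identical(apply_component(comp, u), apply_component(comp, u))

  expect_warning(drift_parameters(compd, 9), "slow")
})
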