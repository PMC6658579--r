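test_that("the modulation families are decreasing with the stated anchors", {
  cfg <- drive_config(sigma_max = 0.4,
                      modulation = list(family = "hill", x_half = 0.3,
                                        steepness = 3))
  expect_equal(modulation_sigma(0, cfg), 0.4)
  expect_equal(modulation_sigma(0.3, cfg), 0.2) # halved at x_half
  grid <- seq(0, 5, by = 0.05)
  expect_true(all(diff(modulation_sigma(grid, cfg)) < 0))

  cfg$modulation$family <- "exponential"
  expect_equal(modulation_sigma(0, cfg), 0.4)
  expect_true(all(diff(modulation_sigma(grid, cfg)) < 0))
  expect_true(all(modulation_sigma(grid, cfg) > 0))
})

test_that("form steps are unbiased with the commanded spread", {
  th <- c(1, -2)
  expect_equal(step_form(th, 0), th)

  set.seed(2)
  steps <- t(replicate(1e4, step_form(th, 0.7) - th))
  se <- 0.7 / sqrt(1e4)
  expect_true(all(abs(colMeans(steps)) < 3 * se))
  expect_equal(unname(apply(steps, 2, sd)), c(0.7, 0.7), tolerance = 0.05)
  # mean squared displacement = sigma^2 * dim
  expect_equal(mean(rowSums(steps^2)), 0.7^2 * 2, tolerance = 0.05)
})

test_that("run_drive is reproducible and degenerates correctly", {
  wc <- two_bump_world()
  cfg <- two_bump_drive_cfg(horizon_steps = 200L)
  expect_identical(run_drive(wc, cfg, seed = 3), run_drive(wc, cfg, seed = 3))

  frozen <- two_bump_drive_cfg(horizon_steps = 100L, sigma_max = 0)
  tr <- run_drive(wc, frozen, seed = 1)
  expect_true(all(vapply(tr$theta, identical, logical(1), tr$theta[[1]])))
  expect_equal(stats::var(tr$f), 0)
})

test_that("a perfect estimator pins the form to a fitness peak", {
  wc <- world_config(dim_form = 2, landscape = list(bump(c(0, 0), 1, 0.6)),
                     init_scale = 0, init_mean = c(0, 0))
  cfg <- drive_config(sigma_max = 0.05,
                      modulation = list(family = "hill", x_half = 0.3,
                                        steepness = 6),
                      horizon_steps = 800, estimate_noise_sd = 0)
  fp <- vapply(1:5, function(s) fitness_to_be(run_drive(wc, cfg, seed = s)),
               numeric(1))
  expect_true(all(fp >= 0.9))
})

test_that("the paired comparison has a null at zero and is antisymmetric", {
  wc <- two_bump_world()
  null_cfg <- two_bump_drive_cfg(horizon_steps = 120L, sigma_max = 0)
  cmp <- compare_conditions(wc, null_cfg, n_seeds = 8, seed = 2, n_perm = 500)
  expect_equal(cmp$mean_diff, 0)
  expect_gt(cmp$p_value, 0.5)

  d <- c(0.2, -0.1, 0.4, 0.05)
  expect_equal(mean(-d), -mean(d)) # label swap negates the paired difference
  p_pos <- fitloop:::sign_flip_p(d, n_perm = 2000, seed = 1)
  p_neg <- fitloop:::sign_flip_p(-d, n_perm = 2000, seed = 1)
  expect_lt(p_pos, p_neg)
})

test_that("modulated steps beat the matched-mean control on the two-bump world", {
  wc <- two_bump_world()
  cfg <- two_bump_drive_cfg(horizon_steps = 800L)
  cmp <- compare_conditions(wc, cfg, n_seeds = 10, seed = 4, n_perm = 2000)
  expect_gt(cmp$mean_diff, 0)
  expect_lt(cmp$p_value, 0.05)
  expect_equal(nrow(cmp$per_seed), 10)
  # glance/tidy accessors
  g <- glance(cmp)
  expect_equal(g$mean_diff, cmp$mean_diff)
  expect_equal(nrow(tidy(cmp)), 20)
})

test_that("trend_test detects a decreasing trend and not a flat one", {
  set.seed(6)
  x <- rep(1:5, each = 10)
  y_dec <- -x + rnorm(50, sd = 0.5)
  tt <- trend_test(x, y_dec, n_perm = 500, alternative = "less", seed = 1)
  expect_lt(tt$p_value, 0.05)
  expect_lt(tt$statistic, 0)

  y_flat <- rnorm(50)
  tt2 <- trend_test(x, y_flat, n_perm = 500, alternative = "less", seed = 1)
  expect_gt(tt2$p_value, 0.05)
})

test_that("full-chain mode runs the estimate through a bank", {
  wc <- world_config(dim_form = 2, landscape = list(bump(c(0, 0), 1, 0.6)),
                     init_scale = 0, init_mean = c(0, 0))
  bank <- estimator_bank(list(identity_comp(2)), output_map = "relu")
  cfg <- two_bump_drive_cfg(horizon_steps = 50L)
  tr <- run_drive(wc, cfg, seed = 1, use_bank = bank)
  expect_true(all(tr$x >= 0))
  expect_equal(nrow(tr), 50)
})
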