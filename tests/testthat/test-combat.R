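test_that("beta/M transforms hit the anchor points and invert exactly", {
  expect_equal(to_mvalues(matrix(0.5)), matrix(0))
  expect_equal(to_mvalues(matrix(0.8)), matrix(2))
  x <- matrix(runif(2000, 0.001, 0.999), 100, 20)
  expect_lt(max(abs(from_mvalues(to_mvalues(x)) - x)), 1e-12)
})

test_that("a single batch level yields an identity correction", {
  x <- matrix(rnorm(600, 5, 2), 100, 6)
  fit <- combat_fit(x, rep(1, 6))
  expect_true(fit$identity)
  expect_lt(max(abs(combat_apply(x, fit) - x)), 1e-6)
})

test_that("a constant additive batch offset is removed up to shrinkage noise", {
  withr::local_seed(13)
  m <- 300
  x <- matrix(rnorm(m * 40, 0, 1), m, 40) + rnorm(m)
  batch <- rep(1:2, each = 20)
  x[, batch == 2] <- x[, batch == 2] + 0.8
  fit <- combat_fit(x, batch)
  out <- combat_apply(x, fit)
  d_before <- rowMeans(x[, batch == 1]) - rowMeans(x[, batch == 2])
  d_after <- rowMeans(out[, batch == 1]) - rowMeans(out[, batch == 2])
  # the shared 0.8 offset is gone from the overall batch means ...
  expect_lt(abs(mean(d_after)), 0.02)
  # ... and per-probe batch differences collapse to the shrunken remnant of
  # their sampling noise (empirical Bayes never zeroes them exactly)
  expect_lt(mean(abs(d_after)), 0.3 * mean(abs(d_before)))
})

test_that("corrected output matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  withr::local_seed(42)
  m <- 200; n <- 12
  x <- matrix(rnorm(m * n), m, n) + rnorm(m)
  batch <- factor(rep(1:2, each = 6))
  grp <- factor(rep(rep(c("control", "case"), each = 3), 2),
                levels = c("control", "case"))
  mod <- model.matrix(~grp)

  ours <- combat_apply(x, combat_fit(x, batch, mod = mod))
  ref <- suppressMessages(sva::ComBat(x, batch, mod = mod, par.prior = TRUE))
  expect_lt(max(abs(ours - ref)), 1e-6)

  ours2 <- combat_apply(x, combat_fit(x, batch))
  ref2 <- suppressMessages(sva::ComBat(x, batch, par.prior = TRUE))
  expect_lt(max(abs(ours2 - ref2)), 1e-6)

  b3 <- factor(rep(1:3, each = 4))
  ours3 <- combat_apply(x, combat_fit(x, b3, mod = mod))
  ref3 <- suppressMessages(sva::ComBat(x, b3, mod = mod, par.prior = TRUE))
  expect_lt(max(abs(ours3 - ref3)), 1e-6)
})

test_that("empirical-Bayes posteriors shrink toward the prior location", {
  withr::local_seed(3)
  x <- matrix(rnorm(500 * 12), 500, 12)
  fit <- combat_fit(x, rep(1:3, each = 4))
  for (i in 1:3) {
    expect_lte(mean(abs(fit$gamma_star[i, ] - fit$gamma_bar[i])),
               mean(abs(fit$gamma_hat[i, ] - fit$gamma_bar[i])))
  }
  expect_true(all(fit$delta_star > 0))
  expect_true(all(fit$converged))
})

test_that("refitting corrected data finds near-zero batch locations", {
  withr::local_seed(8)
  m <- 400
  x <- matrix(rnorm(m * 40), m, 40)
  batch <- rep(1:2, each = 20)
  x[, batch == 2] <- x[, batch == 2] + rnorm(m, 0, 2)  # probe-specific offsets
  fit <- combat_fit(x, batch)
  out <- combat_apply(x, fit)
  refit <- combat_fit(out, batch)
  expect_lt(mean(abs(refit$gamma_hat)), mean(abs(fit$gamma_hat)) / 10)
})

test_that("adjusted matrices stay finite for random inputs", {
  for (seed in 1:3) {
    withr::local_seed(seed)
    x <- matrix(rnorm(100 * 9, sd = runif(1, 0.1, 10)), 100, 9)
    batch <- sample(rep(1:3, each = 3))
    out <- combat_apply(x, combat_fit(x, batch))
    expect_true(all(is.finite(out)))
  }
})

test_that("the nonparametric pathway is explicitly unimplemented", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(combat_fit(x, rep(1:2, each = 2), parametric = FALSE),
               "not implemented")
})

test_that("confounded covariates are dropped with a warning and flagged", {
  withr::local_seed(15)
  x <- matrix(rnorm(200 * 8), 200, 8)
  batch <- rep(1:2, each = 4)
  grp <- factor(rep(c("control", "case"), each = 4))  # identical to batch
  mod <- model.matrix(~grp)
  expect_warning(fit <- combat_fit(x, batch, mod = mod), "confounded")
  expect_true(fit$covariates_dropped)
  # the degraded fit equals the covariate-free fit
  plain <- combat_fit(x, batch)
  expect_equal(combat_apply(x, fit), combat_apply(x, plain), tolerance = 1e-12)
  # every-level-singleton batch errors
  expect_error(combat_fit(x, seq_len(8)), "at least 2 samples")
})

test_that("sequential correction runs the factors in order on the M-value scale", {
  prof <- tiny_profile(400, seed = 51)
  layout <- layout48("random", seed = 4)
  b <- generate_null_betas(prof, layout, seed = 5)
  b <- inject_batch_effects(b, layout, amplitude = 0.01, seed = 6)

  same <- sequential_correct(b, layout, factors = character(0),
                             variant = "no_model")
  expect_identical(same$values, b$values)
  none <- sequential_correct(b, layout, variant = "none")
  expect_identical(none$values, b$values)

  corr <- sequential_correct(b, layout, factors = c("row", "chip"),
                             variant = "no_model")
  expect_equal(corr$provenance, "corrected")
  expect_equal(corr$correction$log$factor, c("row", "chip"))
  expect_equal(corr$correction$log$n_levels, c(8L, 6L))
  expect_true(all(corr$values >= 0.001 & corr$values <= 0.999))

  # the outcome-model variant differs from the covariate-free one
  lu <- layout48("unbalanced")
  bu <- generate_null_betas(prof, lu, seed = 7)
  w <- sequential_correct(bu, lu, variant = "with_outcome_model")
  nm <- sequential_correct(bu, lu, variant = "no_model")
  expect_gt(max(abs(w$values - nm$values)), 0)
  expect_error(sequential_correct(b, layout, factors = "bogus",
                                  variant = "no_model"), "unknown factor")
})

test_that("correction reduces the variance of batch-level means", {
  prof <- tiny_profile(500, seed = 61)
  layout <- layout48("random", seed = 8)
  b <- generate_null_betas(prof, layout, seed = 9)
  b <- inject_batch_effects(b, layout, amplitude = 0.02, seed = 10)
  corr <- sequential_correct(b, layout, factors = "chip", variant = "no_model")
  chip_means_before <- vapply(split(seq_len(48), layout$chip),
                              function(i) mean(b$values[, i]), numeric(1))
  chip_means_after <- vapply(split(seq_len(48), layout$chip),
                             function(i) mean(corr$values[, i]), numeric(1))
  expect_lt(var(chip_means_after), var(chip_means_before))
})

test_that("tidy and glance summarise a correction fit", {
  withr::local_seed(2)
  x <- matrix(rnorm(300), 50, 6)
  fit <- combat_fit(x, rep(1:2, each = 3))
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("gamma_bar", "t2", "a_prior", "b_prior") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_batch, 2L)
  expect_true(gl$converged)
  expect_false(gl$covariates_dropped)
})
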