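test_that("the coefficient of determination follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 2, 9)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2)), 0.97)  # hand arithmetic
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(r_squared(1, 1), "at least 2")
  # accepts volume-series frames
  a <- tibble::tibble(time_days = 0:2, volume_cm3 = c(1, 2, 3))
  b <- tibble::tibble(time_days = 0:2, volume_cm3 = c(1.1, 1.9, 3.2))
  expect_equal(r_squared(a, b), 0.97)
})

test_that("noiseless correction factors are recovered under the probe design", {
  s <- recovery_setting()
  obs <- noiseless_series(0.60, -1.50)
  fit <- fit_correction_factors(obs, s$schedule, s$kinetics)
  expect_lt(abs(fit$corr_a_hat - 0.60) / 0.60, 1e-4)
  expect_lt(abs(fit$corr_b_hat + 1.50) / 1.50, 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("data from the conventional model fit back to A = 1, B = 0", {
  s <- recovery_setting()
  obs <- noiseless_series(1, 0)
  fit <- fit_correction_factors(obs, s$schedule, s$kinetics)
  expect_equal(fit$corr_a_hat, 1, tolerance = 1e-4)
  expect_equal(fit$corr_b_hat, 0, tolerance = 1e-4)
  expect_equal(conventional_prediction_score(obs, s$schedule, s$kinetics), 1,
               tolerance = 1e-12)
})

test_that("the fitted model never scores below the conventional comparator", {
  s <- recovery_setting()
  set.seed(41)
  for (i in 1:10) {
    spec <- synthetic_patient(
      v0 = runif(1, 7.6, 375.2), t_half = runif(1, 13.9, 90.6),
      corr_a = runif(1, 0.15, 0.9), corr_b = runif(1, -3, -0.4),
      schedule = s$schedule, sample_times = s$sample_times,
      noise_cv = 0.05, seed = 1000 + i)
    obs <- generate_trajectory(spec)[c("time_days", "volume_cm3")]
    cmp <- compare_models(obs, s$schedule, kinetic_params(spec$t_pot, spec$t_half))
    expect_gte(cmp$r_squared, cmp$r0_squared - 1e-10)
  }
})

test_that("the reported objective equals the recomputed residual sum of squares", {
  s <- recovery_setting()
  obs <- generate_trajectory(synthetic_patient(
    corr_a = 0.5, corr_b = -1, schedule = s$schedule,
    sample_times = s$sample_times, noise_cv = 0.05, seed = 7
  ))[c("time_days", "volume_cm3")]
  fit <- fit_correction_factors(obs, s$schedule, s$kinetics)
  pred <- simulate_course(s$schedule, obs$time_days, obs$volume_cm3[1],
                          lq_params(corr_a = fit$corr_a_hat,
                                    corr_b = fit$corr_b_hat),
                          s$kinetics)$volume_cm3
  expect_equal(fit$objective, sum((obs$volume_cm3 - pred)^2), tolerance = 1e-12)
  expect_equal(fit$residuals$residual_cm3, obs$volume_cm3 - pred,
               tolerance = 1e-12)
})

test_that("identical inputs give bit-identical fits", {
  s <- recovery_setting()
  obs <- generate_trajectory(synthetic_patient(
    schedule = s$schedule, sample_times = s$sample_times, seed = 99
  ))[c("time_days", "volume_cm3")]
  f1 <- fit_correction_factors(obs, s$schedule, s$kinetics)
  f2 <- fit_correction_factors(obs, s$schedule, s$kinetics)
  expect_identical(f1[c("corr_a_hat", "corr_b_hat", "r_squared", "objective")],
                   f2[c("corr_a_hat", "corr_b_hat", "r_squared", "objective")])
})

test_that("fitting demands enough timepoints and sane bounds", {
  s <- recovery_setting()
  two <- tibble::tibble(time_days = c(0, 14), volume_cm3 = c(80, 60))
  expect_error(fit_correction_factors(two, s$schedule, s$kinetics),
               "3 measured timepoints")
  obs <- noiseless_series(0.5, -1)
  expect_error(fit_correction_factors(obs, s$schedule, s$kinetics,
                                      corr_a_bounds = c(-1, 2)),
               "strictly positive")
  expect_error(fit_correction_factors(obs, s$schedule, s$kinetics,
                                      corr_b_bounds = c(-Inf, 1)),
               "finite")
})

test_that("relative-residual fitting recovers the same parameters", {
  s <- recovery_setting()
  obs <- noiseless_series(0.6, -1.5)
  fit <- fit_correction_factors(obs, s$schedule, s$kinetics,
                                residual_space = "relative")
  expect_equal(fit$corr_a_hat, 0.6, tolerance = 1e-4)
  expect_equal(fit$corr_b_hat, -1.5, tolerance = 1e-4)
})

test_that("cohort summaries report plain and nonnegative-only means", {
  out <- summarize_cohort(c(7.6, 27.4, 97.7, 189.3))
  expect_equal(out$mean, 80.5)
  expect_equal(summarize_cohort(c(13.9, 90.6, 15.6, 24.4, 31.0))$mean, 35.1)
  expect_equal(summarize_cohort(5)$mean, 5)
  mixed <- summarize_cohort(c(0.52, 0.43, -0.68, 0.94))
  expect_equal(mixed$mean, mean(c(0.52, 0.43, -0.68, 0.94)))
  expect_equal(mixed$mean_nonnegative, mean(c(0.52, 0.43, 0.94)))
  expect_equal(mixed$n_nonnegative, 3)
  expect_error(summarize_cohort(numeric()), "non-empty")
})

test_that("broom-style accessors expose estimates, diagnostics and residuals", {
  s <- recovery_setting()
  obs <- noiseless_series(0.6, -1.5)
  cmp <- compare_models(obs, s$schedule, s$kinetics)
  td <- tidy(cmp)
  expect_equal(td$term, c("corr_a", "corr_b"))
  expect_equal(td$estimate, c(0.6, -1.5), tolerance = 1e-4)
  gl <- glance(cmp)
  expect_true(all(c("r_squared", "r0_squared", "objective", "converged") %in%
                    names(gl)))
  expect_equal(gl$r_squared, 1, tolerance = 1e-10)
  au <- augment(cmp$fit)
  expect_equal(nrow(au), nrow(obs))
  expect_equal(au$measured_cm3 - au$predicted_cm3, au$residual_cm3)
  p <- ggplot2::autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
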