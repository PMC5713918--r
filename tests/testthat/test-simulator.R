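test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- simulate_patient(preset_params("worst", seed = 11, duration = 60))
  b <- simulate_patient(preset_params("worst", seed = 11, duration = 60))
  expect_identical(a$external$values, b$external$values)
  expect_identical(a$imaging$Y, b$imaging$Y)
  c <- simulate_patient(preset_params("worst", seed = 12, duration = 60))
  expect_gt(max(abs(a$external$values - c$external$values)), 0.1)
  # simulating must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_patient(preset_params("control", 5, 30)))
  expect_identical(rnorm(1), before)
})

test_that("zero-noise affine coupling leaves no affine residual", {
  pat <- make_linear_patient(seed = 5, n_imaging = 20, duration = 120)
  fit <- stats::lm.fit(cbind(pat$external$values, 1),
                       pat$internal_truth$values)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # and the imaging pairs inherit exactness
  fit2 <- stats::lm.fit(cbind(pat$imaging$X, 1), pat$imaging$Y)
  expect_lt(max(abs(fit2$residuals)), 1e-9)
})

test_that("the breathing spectrum peaks at the configured rate", {
  p <- breathing_params(period_mean = 4, period_jitter_sd = 0,
                        amplitude_jitter_sd = 0, external_noise_sd = 0,
                        drift_rate = 0, duration = 300, seed = 3)
  pat <- simulate_patient(p)
  z <- pat$external$values[, 3]          # SI channel of marker 1
  z <- z - mean(z)
  sp <- stats::spec.pgram(stats::ts(z, frequency = 25), plot = FALSE,
                          taper = 0, detrend = TRUE)
  peak <- sp$freq[which.max(sp$spec)]
  expect_equal(peak, 0.25, tolerance = 0.02)
})

test_that("amplitude scaling is exactly linear in the oscillatory component", {
  base <- breathing_params(period_jitter_sd = 0, amplitude_jitter_sd = 0,
                           external_noise_sd = 0, drift_rate = 0,
                           duration = 60, seed = 6)
  doubled <- base
  doubled$amplitudes <- 2 * base$amplitudes
  p1 <- simulate_patient(base)
  p2 <- simulate_patient(doubled)
  osc1 <- sweep(p1$external$values, 2, base$baseline, "-")
  osc2 <- sweep(p2$external$values, 2, base$baseline, "-")
  expect_equal(osc2, 2 * osc1, tolerance = 1e-12)
})

test_that("imaging schedules cover the clinical regimes", {
  # minimum regime: 4 points over 58 s
  pat_min <- simulate_patient(preset_params("control", seed = 2,
                                            duration = 58), n_imaging = 4)
  expect_equal(nrow(pat_min$imaging$X), 4L)
  # maximum regime: 27 points over 603 s
  pat_max <- simulate_patient(preset_params("control", seed = 2,
                                            duration = 603), n_imaging = 27)
  expect_equal(nrow(pat_max$imaging$X), 27L)
  # uniform schedule: gaps equal span/(n-1) up to one sample period
  ts <- pat_max$imaging$timestamps
  gap <- 603 / 26
  expect_true(all(abs(diff(ts) - gap) <= 1 / 25 + 1e-9))
  # all schedules produce time-ordered sets of the right size
  for (sched in c("uniform", "random", "burst")) {
    im <- sample_imaging(pat_min, 5, schedule = sched, seed = 4)
    expect_equal(nrow(im$X), 5L)
    expect_true(all(diff(im$timestamps) > 0))
  }
  expect_error(sample_imaging(pat_min, 1e6), "exceeds")
})

test_that("cohorts regenerate identically and pass trace invariants", {
  co1 <- make_cohort(presets = rep(c("control", "worst"), each = 2),
                     seed = 5, duration = 60, n_imaging = 6)
  co2 <- make_cohort(presets = rep(c("control", "worst"), each = 2),
                     seed = 5, duration = 60, n_imaging = 6)
  for (i in seq_along(co1)) {
    expect_identical(co1[[i]]$external$values, co2[[i]]$external$values)
    # constructors enforce invariants; these objects exist, so they passed
    expect_s3_class(co1[[i]]$external, "marker_trace")
    expect_s3_class(co1[[i]]$imaging, "training_set")
    expect_identical(co1[[i]]$preset,
                     rep(c("control", "worst"), each = 2)[i])
  }
})

test_that("hysteresis opens an inhale/exhale loop no affine map closes", {
  base <- breathing_params(period_jitter_sd = 0, amplitude_jitter_sd = 0,
                           external_noise_sd = 0, internal_noise_sd = 0,
                           drift_rate = 0, duration = 60, seed = 8, lag = 0)
  hyst <- base; hyst$hysteresis <- 0.4
  p0 <- simulate_patient(base); ph <- simulate_patient(hyst)
  # with hysteresis the internal SI is no longer a function of external SI:
  # the best affine fit now leaves a visible residual
  r0 <- stats::lm.fit(cbind(p0$external$values, 1),
                      p0$internal_truth$values[, 3])$residuals
  rh <- stats::lm.fit(cbind(ph$external$values, 1),
                      ph$internal_truth$values[, 3])$residuals
  expect_lt(max(abs(r0)), 1e-9)
  expect_gt(stats::sd(rh), 0.1)
})
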