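test_that("preprocessing resamples onto the grid and removes the steady state", {
  # already-uniform input: values unchanged at grid points
  ev <- make_events(seq(0, 1, by = 0.01), x = sin(seq(0, 1, by = 0.01)))
  pre <- preprocess_stroke(ev, grid_ms = 10)
  expect_equal(pre$x + pre$steady_state, ev$x_mm)
  # constant signal: all zeros after detrend
  flat <- make_events(seq(0, 1, by = 0.01), x = 5)
  expect_equal(preprocess_stroke(flat)$x, rep(0, 101))
  # too-short stroke
  expect_error(preprocess_stroke(make_events(c(0, 0.01), x = c(0, 1))),
               "too short")
})

test_that("noiseless generator strokes reduce to the damped sinusoid", {
  # long stroke so the final-10% mean equals the asymptote to ~1e-9
  cfg <- quiet_config(zeta = 0.7, omega_d = 10, duration = 8)
  set.seed(61)
  ev <- simulate_stroke(click_trial(1000), cfg)
  pre <- preprocess_stroke(ev, grid_ms = 10)
  D <- 100
  omega_n <- 10 / sqrt(1 - 0.49)
  t <- pre$t_s - pre$t_s[1]
  sinusoid <- -D * exp(-0.7 * omega_n * t) *
    (cos(10 * t) + (0.7 * omega_n / 10) * sin(10 * t))
  expect_lt(max(abs(pre$x - sinusoid)), 1e-9)
})

test_that("AR(2) fitting recovers exact linear recurrences", {
  # x[n] = 1.7 x[n-1] - 0.8 x[n-2], no noise
  x <- numeric(60); x[1] <- 1; x[2] <- 1.5
  for (n in 3:60) x[n] <- 1.7 * x[n - 1] - 0.8 * x[n - 2]
  fit <- fit_ar2(x)
  expect_equal(fit$a1, 1.7, tolerance = 1e-9)
  expect_equal(fit$a2, -0.8, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-10)

  # damped sinusoid r^n cos(n theta) has poles r e^{+-i theta}
  r <- 0.93; theta <- 0.4
  n <- 0:80
  fit <- fit_ar2(r^n * cos(n * theta))
  expect_equal(sort(Mod(fit$poles)), rep(r, 2), tolerance = 1e-8)
  expect_equal(abs(Arg(fit$poles[1])), theta, tolerance = 1e-8)

  expect_error(fit_ar2(rep(2, 50)), "constant")
  expect_error(fit_ar2(c(1, 2, 3)), "at least 8")
})

test_that("white noise gives decaying poles and large residuals", {
  set.seed(62)
  x <- rnorm(500)
  fit <- fit_ar2(x)
  expect_true(all(Mod(fit$poles) < 1))
  expect_gt(fit$residual_rms, 0.5)
})

test_that("pole mapping matches the closed form", {
  # r = 0.9, theta = 0.1, dt = 10 ms -> s = -10.536 +- 10.000i
  r <- 0.9; theta <- 0.1
  fit <- structure(list(poles = complex(modulus = c(r, r),
                                        argument = c(theta, -theta))),
                   class = "ar2_fit")
  p <- ar2_to_msd(fit, dt_s = 0.01)
  expect_equal(p$omega_rad_s, 10.000, tolerance = 1e-9)
  expect_equal(p$gamma, 0.7253, tolerance = 1e-4)
  expect_equal(p$regime, "underdamped")
  expect_true(p$stable)

  # double real pole: a1 = 1.8, a2 = -0.81 -> overdamped flag
  fit2 <- fit_ar2_coeffs(1.8, -0.81)
  p2 <- ar2_to_msd(fit2, 0.01)
  expect_equal(p2$regime, "overdamped_flagged")
  expect_true(is.na(p2$gamma))

  # |z| = 1: no decay, flagged unstable
  fit3 <- structure(list(poles = complex(modulus = c(1, 1),
                                         argument = c(0.3, -0.3))),
                    class = "ar2_fit")
  p3 <- ar2_to_msd(fit3, 0.01)
  expect_false(p3$stable)
  expect_equal(p3$gamma, 0, tolerance = 1e-12)
})

test_that("trial-level estimation recovers generator ground truth", {
  cfg <- quiet_config(zeta = 0.5, omega_d = 8, duration = 2)
  set.seed(63)
  ev <- simulate_stroke(click_trial(512), cfg)
  st <- split_strokes(ev)
  est <- estimate_trial_msd(st)
  expect_equal(est$gamma, 0.5, tolerance = 1e-4)
  expect_equal(est$omega_rad_s, 8, tolerance = 0.01)
  expect_equal(est$flag, "")

  # tiny trial: flagged absent, not an error
  tiny <- split_strokes(make_events(c(0, 0.01, 0.02), x = c(0, 1, 2)),
                        segmentation_config(min_stroke_samples = 3))
  est2 <- estimate_trial_msd(tiny)
  expect_true(is.na(est2$gamma))
  expect_true(nzchar(est2$flag))
  # empty stroke list
  expect_equal(estimate_trial_msd(list())$flag, "no_valid_stroke")
})

test_that("MSD estimates are scale invariant and grid consistent", {
  cfg <- quiet_config(zeta = 0.6, omega_d = 10, duration = 2)
  set.seed(64)
  ev <- simulate_stroke(click_trial(1000), cfg)
  base <- msd_fit(ev)
  scaled <- ev; scaled$x_mm <- ev$x_mm * 3.7
  fs <- msd_fit(scaled)
  expect_equal(fs$params$gamma, base$params$gamma, tolerance = 1e-10)
  expect_equal(fs$params$omega_rad_s, base$params$omega_rad_s,
               tolerance = 1e-10)

  half <- msd_fit(ev, grid_ms = 5)
  expect_equal(half$params$gamma, base$params$gamma, tolerance = 0.01)
  expect_equal(half$params$omega_rad_s, base$params$omega_rad_s,
               tolerance = 0.01 * base$params$omega_rad_s)
})

test_that("msd_fit behaves like a classed model object", {
  cfg <- quiet_config(zeta = 0.5, omega_d = 8, duration = 2)
  set.seed(65)
  fit <- msd_fit(simulate_stroke(click_trial(1000), cfg))
  co <- coef(fit)
  expect_named(co, c("gamma", "omega_rad_s", "a1", "a2"))
  expect_equal(unname(co[["gamma"]]), 0.5, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_length(fitted(fit), length(fit$pre$x) - 2)
  pred <- predict(fit, type = "response")
  expect_equal(length(pred), length(fit$pre$x))
  # implied step response tracks the observed trajectory
  obs <- fit$pre$x + fit$pre$steady_state
  expect_lt(max(abs(pred - obs)), 0.01 * 100)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_named(sims[[1]], c("t_s", "x_mm"))
  expect_output(print(fit), "Gamma")
  expect_output(print(summary(fit)), "underdamped")
})
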