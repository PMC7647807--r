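test_that("task schedule has the study's block structure", {
  cfg <- generator_config(n_subjects = 4, seed = 7)
  sched <- generate_task_schedule(2, "tStressed", cfg)

  expect_equal(nrow(sched), 120L)
  expect_equal(as.vector(table(sched$task_type)), rep(40L, 3))
  for (tt in c("click", "drag_and_drop", "steer")) {
    sub <- sched[sched$task_type == tt, ]
    expect_equal(nrow(unique(sub[, c("distance_px", "width_px")])), 20L)
    expect_equal(as.vector(table(sub$repetition)), c(20L, 20L))
    # contiguous block
    expect_equal(diff(range(sub$order_index)), 39)
  }
  expect_equal(sched$order_index, seq_len(120))
  # widths per task type follow the design table
  expect_true(all(sched$width_px[sched$task_type == "click"] %in% c(8, 16, 32, 64)))
  expect_true(all(sched$width_px[sched$task_type == "drag_and_drop"] %in% c(16, 32, 64, 128)))
  expect_true(all(sched$distance_px %in% c(64, 128, 256, 512, 1024)))
})

test_that("task schedule is deterministic in the seed and varies by subject", {
  cfg <- generator_config(n_subjects = 4, seed = 3)
  expect_identical(generate_task_schedule(1, "tRelaxed", cfg),
                   generate_task_schedule(1, "tRelaxed", cfg))
  s1 <- generate_task_schedule(1, "tRelaxed", cfg)
  s2 <- generate_task_schedule(2, "tRelaxed", cfg)
  expect_false(identical(s1$task_type, s2$task_type) &&
                 identical(s1$distance_px, s2$distance_px))
})

test_that("simulated strokes follow the underdamped step response", {
  # noiseless, grid-aligned sampling: trajectory is the closed form exactly
  cfg <- quiet_config(zeta = 0.5, omega_d = 8, duration = 3)
  set.seed(1)
  ev <- simulate_stroke(click_trial(1000), cfg)
  D <- 1000 * cfg$px_to_mm
  t <- ev$t_s - ev$t_s[1]
  expected <- ev$x_mm[1] + msd_step_response(t, D, 0.5, 8)
  expect_equal(ev$x_mm, expected, tolerance = 1e-12)
  # starts at rest
  expect_equal(ev$x_mm[1] - expected[1], 0)
  # settles to within 1% of D after 5 time constants
  omega_n <- 8 / sqrt(1 - 0.25)
  settled <- t >= 5 / (0.5 * omega_n)
  expect_true(all(abs(ev$x_mm[settled] - (ev$x_mm[1] + D)) < 0.01 * D))
})

test_that("low damping overshoots the target; high zeta is rejected", {
  cfg <- quiet_config(zeta = 0.3, omega_d = 8, duration = 3)
  set.seed(2)
  ev <- simulate_stroke(click_trial(1000), cfg)
  D <- 100
  expect_gt(max(ev$x_mm) - ev$x_mm[1], D)
  expect_error(generator_config(true_msd = list(
    tRelaxed = list(zeta = 1.2, omega_d = 8),
    tStressed = list(zeta = 0.5, omega_d = 8))), "underdamped")
  bad <- quiet_config()
  expect_no_error(simulate_stroke(click_trial(), bad, t0_s = 0))
  bad$stroke_duration_s <- -1
  expect_error(simulate_stroke(click_trial(), bad), "duration")
})

test_that("contact areas realize the configured mean and SD", {
  cfg <- generator_config(seed = 5)
  set.seed(10)
  ev <- do.call(rbind, replicate(30, simulate_stroke(click_trial(), cfg),
                                 simplify = FALSE))
  areas <- pi * ev$major_mm * ev$minor_mm
  expect_equal(mean(areas), cfg$area_model$mean[["tRelaxed"]],
               tolerance = 0.02)
  expect_equal(sd(areas), cfg$area_model$within_sd[["tRelaxed"]],
               tolerance = 0.15)
  expect_true(all(ev$major_mm >= ev$minor_mm))
})

test_that("artifact injection honours the gap probability", {
  cfg0 <- generator_config(gap_probability = 0)
  set.seed(3)
  ev <- simulate_stroke(click_trial(), cfg0)
  out <- inject_artifacts(ev, cfg0)
  expect_equal(out$x_mm, ev$x_mm)
  expect_false(attr(out, "gap_injected"))

  cfg1 <- generator_config(gap_probability = 1)
  set.seed(4)
  for (i in 1:20) {
    ev <- simulate_stroke(click_trial(), cfg1)
    out <- inject_artifacts(ev, cfg1)
    has_discontinuity <- length(unique(out$finger_id)) > 1 ||
      any(diff(out$t_s) * 1000 > 50)
    expect_true(has_discontinuity)
  }
})

test_that("EDA simulation orders conditions and reports ground truth", {
  cfg <- generator_config(seed = 6)
  set.seed(11)
  relaxed <- simulate_eda(300, "tRelaxed", cfg)
  stressed <- simulate_eda(300, "tStressed", cfg)
  expect_gt(mean(stressed$eda_uS), mean(relaxed$eda_uS))
  expect_equal(length(relaxed$truth$scr_times), length(relaxed$truth$scr_amps))
  expect_error(simulate_eda(0, "tRelaxed", cfg), "positive")

  # no SCRs, no noise: the series is the pure tonic drift
  cfg0 <- cfg
  cfg0$eda_model$scr_rate_hz <- c(tRelaxed = 0, tStressed = 0)
  cfg0$eda_model$noise_sd_uS <- 0
  flat <- simulate_eda(120, "tRelaxed", cfg0)
  drift <- cfg0$eda_model$tonic_uS[["tRelaxed"]] +
    cfg0$eda_model$drift_uS_per_min * flat$t_s / 60
  expect_equal(flat$eda_uS, drift, tolerance = 1e-12)
})

test_that("simulate_study assembles a reproducible two-arm dataset", {
  cfg <- generator_config(n_subjects = 2, seed = 21)
  study <- simulate_study(cfg)
  expect_length(study$subjects, 2)
  for (subj in study$subjects) {
    n_tr <- sum(vapply(subj$conditions,
                       function(cc) nrow(cc$annotations), 0L))
    expect_equal(n_tr, 240L)
    expect_equal(nrow(subj$self_reports), 6L)
    expect_true(all(subj$self_reports$stress %in% 0:10))
    expect_setequal(subj$self_reports$marker, paste0("SR", 0:5))
  }
  # arm assignment honoured
  expect_equal(vapply(study$subjects, function(s) s$arm, ""),
               cfg$arm_assignment)
  # byte-identical reproduction from the same config
  study2 <- simulate_study(cfg)
  expect_identical(serialize(study, NULL), serialize(study2, NULL))
  expect_error(simulate_study(generator_config(n_subjects = 1)),
               "paired")
})

test_that("default arm split is 8/10 at 18 subjects", {
  cfg <- generator_config()
  expect_equal(sum(cfg$arm_assignment == "Relax-Stress"), 8L)
  expect_equal(sum(cfg$arm_assignment == "Stress-Relax"), 10L)
})

test_that("configured standardized area effect is recovered at large n", {
  # 1000 subjects, subject-level area means drawn as the generator draws
  # them: relaxed = mu + baseline, stressed = relaxed + d * between_sd
  cfg <- generator_config(effect_spec = list(d_area_mean = 0.6), seed = 8)
  expect_equal(cfg$area_model$mean[["tStressed"]],
               270.9 + 0.6 * cfg$area_model$between_sd)
  set.seed(12)
  n <- 1000
  baseline <- rnorm(n, 0, cfg$area_model$between_sd)
  x <- cfg$area_model$mean[["tRelaxed"]] + baseline
  y <- cfg$area_model$mean[["tStressed"]] + baseline
  # trial-averaging noise is second-order; add the per-subject SE of a
  # 40-trial click mean to mimic the measured phase values
  x <- x + rnorm(n, 0, cfg$area_model$within_sd[["tRelaxed"]] / sqrt(40))
  y <- y + rnorm(n, 0, cfg$area_model$within_sd[["tStressed"]] / sqrt(40))
  expect_equal(cohens_d(x, y)$d, 0.6, tolerance = 0.15)
})
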