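# Synthetic study generator: emulates the trackpad logger, self-reports and
# wrist EDA of a two-arm counterbalanced stress study with known ground truth.

# Deterministic small-integer seed derivation (kept < 2^31).
derive_seed <- function(base, ...) {
  ks <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in ks) s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# Truncated-normal positive draws (rejection; vectorised).
rtrunc_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Generate one condition block's task schedule
#'
#' Builds the 120-trial schedule (3 task types x 20 distance/width
#' configurations x 2 repetitions) for one subject and condition. Task-type
#' blocks are contiguous — tasks of the same type are grouped — with the
#' block order randomized per subject and the configuration order randomized
#' within each block.
#'
#' @param subject_id Subject identifier (integer).
#' @param condition `"tRelaxed"` or `"tStressed"`.
#' @param config A [generator_config()].
#' @return A data frame of trial specifications: `trial_id`, `subject_id`,
#'   `condition`, `task_type`, `distance_px`, `width_px`, `repetition`,
#'   `order_index`.
#' @export
generate_task_schedule <- function(subject_id, condition, config) {
  validate_generator_config(config)
  condition <- match.arg(condition, condition_levels())
  set.seed(derive_seed(config$seed, 101L, subject_id,
                       match(condition, condition_levels())))
  block_order <- sample(task_type_levels())
  blocks <- lapply(block_order, function(tt) {
    cfgs <- task_configs(tt)
    reps <- rbind(cbind(cfgs, repetition = 1L), cbind(cfgs, repetition = 2L))
    reps[sample(nrow(reps)), , drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  out$order_index <- seq_len(nrow(out))
  out$subject_id <- subject_id
  out$condition <- condition
  out$trial_id <- sprintf("S%02d_%s_T%03d", subject_id,
                          substr(condition, 2, 2), out$order_index)
  rownames(out) <- NULL
  out[, c("trial_id", "subject_id", "condition", "task_type",
          "distance_px", "width_px", "repetition", "order_index")]
}

#' Simulate one trial's primary finger stroke
#'
#' The horizontal trajectory follows the underdamped step response of a
#' single-degree-of-freedom mass-spring-damper system,
#' \deqn{x(t) = D[1 - e^{-\zeta\omega_n t}(\cos\omega_d t +
#'   \frac{\zeta\omega_n}{\omega_d}\sin\omega_d t)],}
#' with \eqn{\omega_n = \omega_d/\sqrt{1-\zeta^2}}, sampled at jittered
#' intervals and overlaid with additive positional noise. Contact-ellipse
#' axes are drawn as correlated lognormals so that the ellipse area
#' \eqn{\pi a b} has the configured per-condition mean and within-trial SD;
#' y stays near-constant (the tasks are horizontal).
#'
#' @param trial A list or one-row data frame with at least `condition`,
#'   `distance_px` and `task_type`; an optional `area_mean_mm2` overrides the
#'   per-condition area mean (used to carry subject baselines).
#' @param config A [generator_config()].
#' @param t0_s Start time of the stroke, seconds.
#' @param finger_id Finger identifier for the emitted events.
#' @return A data frame of touch events (`t_s`, `finger_id`, `x_mm`, `y_mm`,
#'   `major_mm`, `minor_mm`, `state`, `pressed`).
#' @export
simulate_stroke <- function(trial, config, t0_s = 0, finger_id = 1L) {
  condition <- match.arg(trial$condition, condition_levels())
  msd <- config$true_msd[[condition]]
  if (msd$zeta <= 0 || msd$zeta >= 1)
    stop("generator emits only underdamped trajectories (zeta in (0,1))", call. = FALSE)
  if (config$stroke_duration_s <= 0) stop("non-positive stroke duration", call. = FALSE)
  D <- trial$distance_px * config$px_to_mm
  if (D <= 0) stop("distance must be positive", call. = FALSE)

  dur <- config$stroke_duration_s
  n_max <- ceiling(dur / (config$sampling_mean_ms / 1000)) + 10L
  dts <- rtrunc_pos(n_max, config$sampling_mean_ms, config$sampling_sd_ms,
                    lower = 0.5) / 1000
  t <- cumsum(c(0, dts))
  t <- t[t <= dur]

  x <- msd_step_response(t, D, msd$zeta, msd$omega_d)
  if (config$position_noise_mm > 0)
    x <- x + rnorm(length(t), 0, config$position_noise_mm)
  # start far enough left that the stroke, overshoot included, stays on the
  # pad (clipping would distort the second-order dynamics)
  overshoot <- 1 + exp(-msd$zeta * pi / sqrt(1 - msd$zeta^2))
  x0 <- runif(1, 5, max(5.01, 138 - D * overshoot))
  x <- pmin(pmax(x0 + x, 0), 140)
  y <- pmin(pmax(runif(1, 20, 50) + rnorm(length(t), 0, 0.1), 0), 70)

  area_mean <- if (!is.null(trial$area_mean_mm2)) trial$area_mean_mm2 else
    config$area_model$mean[[condition]]
  within_sd <- config$area_model$within_sd[[condition]]
  areas <- rlnorm_moments(length(t), area_mean, within_sd)
  aspect <- pmax(exp(rnorm(length(t), config$area_model$aspect_meanlog,
                           config$area_model$aspect_sdlog)), 1)
  major <- sqrt(areas * aspect / pi)
  minor <- sqrt(areas / (aspect * pi))

  state <- if (identical(trial$task_type, "click")) "touching" else "dragging"
  data.frame(t_s = t0_s + t, finger_id = as.integer(finger_id),
             x_mm = x, y_mm = y, major_mm = major, minor_mm = minor,
             state = state, pressed = TRUE, stringsAsFactors = FALSE)
}

#' Underdamped step response of a mass-spring-damper system
#'
#' @param t Time vector, seconds (response starts at rest at t = 0).
#' @param D Step size (target displacement).
#' @param zeta Damping ratio in (0,1).
#' @param omega_d Damped frequency, rad/s.
#' @return Displacement at `t`.
#' @export
msd_step_response <- function(t, D, zeta, omega_d) {
  omega_n <- omega_d / sqrt(1 - zeta^2)
  D * (1 - exp(-zeta * omega_n * t) *
         (cos(omega_d * t) + (zeta * omega_n / omega_d) * sin(omega_d * t)))
}

# Lognormal draws with given arithmetic mean and SD (moment matching).
rlnorm_moments <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Inject multi-finger artifacts into a trial's events
#'
#' Emulates the discontinuities real subjects produce: with probability
#' `gap_probability` a contiguous 50-300 ms span inside the middle 80% of the
#' trial is removed and all later events are re-labelled with a fresh
#' `finger_id` (a lift-and-replace). With probability 0.3 a short concurrent
#' secondary trace from another finger is added; its x-extent is kept small
#' so the largest continuous stroke of the trial is unchanged.
#'
#' @param events Time-sorted event data frame from [simulate_stroke()].
#' @param config A [generator_config()].
#' @return The event data frame with artifacts applied (attribute
#'   `"gap_injected"` records whether a gap was injected).
#' @export
inject_artifacts <- function(events, config) {
  stopifnot(nrow(events) > 0)
  gap <- runif(1) < config$gap_probability
  if (gap) {
    t0 <- min(events$t_s); t1 <- max(events$t_s)
    span <- runif(1, 0.05, 0.3)
    lo_min <- t0 + 0.1 * (t1 - t0)
    lo_max <- max(lo_min, t1 - 0.1 * (t1 - t0) - span)
    lo <- runif(1, lo_min, lo_max)
    drop <- events$t_s >= lo & events$t_s < lo + span
    # never drop the trial outright; keep at least the endpoints
    if (any(drop) && sum(!drop) >= 4) {
      after <- events$t_s >= lo + span
      events$finger_id[after] <- events$finger_id[after] + 1L
      events <- events[!drop, , drop = FALSE]
    } else {
      # too few events to carve: force a lift by re-labelling the tail
      half <- events$t_s >= (t0 + t1) / 2
      events$finger_id[half] <- events$finger_id[half] + 1L
    }
  }
  if (gap && runif(1) < 0.3 && nrow(events) >= 10) {
    # concurrent short secondary trace (resting finger), tiny displacement
    t0 <- min(events$t_s); t1 <- max(events$t_s)
    s0 <- runif(1, t0, max(t0, t1 - 0.2))
    ts <- seq(s0, min(s0 + runif(1, 0.08, 0.2), t1),
              by = config$sampling_mean_ms / 1000)
    if (length(ts) >= 2) {
      xs <- runif(1, 5, 135) + cumsum(rnorm(length(ts), 0, 0.05))
      area <- rlnorm_moments(length(ts),
                             mean(config$area_model$mean), 5)
      aspect <- pmax(exp(rnorm(length(ts), config$area_model$aspect_meanlog,
                               config$area_model$aspect_sdlog)), 1)
      sec <- data.frame(t_s = ts,
                        finger_id = max(events$finger_id) + 1L,
                        x_mm = pmin(pmax(xs, 0), 140),
                        y_mm = pmin(pmax(runif(1, 5, 65), 0), 70),
                        major_mm = sqrt(area * aspect / pi),
                        minor_mm = sqrt(area / (aspect * pi)),
                        state = "touching", pressed = FALSE,
                        stringsAsFactors = FALSE)
      events <- rbind(events, sec)
      events <- events[order(events$t_s), , drop = FALSE]
    }
  }
  rownames(events) <- NULL
  attr(events, "gap_injected") <- gap
  events
}

#' Simulate an electrodermal activity series for one phase
#'
#' Skin conductance is modelled as a tonic level with slow linear drift plus
#' a sum of skin-conductance-response (SCR) pulses with biexponential
#' rise/decay shape and lognormal amplitudes, plus Gaussian sensor noise,
#' sampled at the wearable's 4 Hz EDA rate. The stressed condition uses a
#' higher tonic level, SCR rate and pulse amplitudes. Ground-truth pulse
#' times and amplitudes are returned alongside the series.
#'
#' @param phase_duration_s Phase duration, seconds (> 0).
#' @param condition `"tRelaxed"` or `"tStressed"`.
#' @param config A [generator_config()].
#' @return An object of class `"eda_series"`: list with `t_s`, `eda_uS`,
#'   `sample_rate_hz` and a `truth` list (`scr_times`, `scr_amps`,
#'   `tonic_level`).
#' @export
simulate_eda <- function(phase_duration_s, condition, config) {
  if (phase_duration_s <= 0) stop("phase duration must be positive", call. = FALSE)
  condition <- match.arg(condition, condition_levels())
  em <- config$eda_model
  fs <- em$sample_rate_hz
  t <- seq(0, phase_duration_s, by = 1 / fs)
  tonic <- em$tonic_uS[[condition]] + em$drift_uS_per_min * t / 60
  n_scr <- rpois(1, em$scr_rate_hz[[condition]] * phase_duration_s)
  scr_times <- sort(runif(n_scr, 0, max(phase_duration_s - 5, 0.5)))
  scr_amps <- rlnorm(n_scr, em$amp_meanlog[[condition]], em$amp_sdlog)
  phasic <- scr_pulse_train(t, scr_times, scr_amps, em$rise_s, em$decay_s)
  eda <- tonic + phasic + rnorm(length(t), 0, em$noise_sd_uS)
  structure(list(t_s = t, eda_uS = pmax(eda, 0), sample_rate_hz = fs,
                 truth = list(scr_times = scr_times, scr_amps = scr_amps,
                              tonic_level = em$tonic_uS[[condition]])),
            class = "eda_series")
}

#' Sum of biexponential SCR pulses, each normalized to its peak amplitude
#' @param t Time grid, seconds.
#' @param times,amps Pulse onset times and peak amplitudes.
#' @param rise_s,decay_s Rise and decay time constants (decay > rise).
#' @return Phasic signal on `t`.
#' @export
scr_pulse_train <- function(t, times, amps, rise_s, decay_s) {
  stopifnot(decay_s > rise_s)
  # peak of exp(-u/d) - exp(-u/r) for unit-scaled shape
  t_pk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  pk <- exp(-t_pk / decay_s) - exp(-t_pk / rise_s)
  out <- numeric(length(t))
  for (i in seq_along(times)) {
    u <- t - times[i]
    pos <- u > 0
    out[pos] <- out[pos] +
      amps[i] * (exp(-u[pos] / decay_s) - exp(-u[pos] / rise_s)) / pk
  }
  out
}

# Truncated discretized normal on the 0-10 self-report scale.
rself_report <- function(n, mean, sd) {
  pmin(pmax(round(rnorm(n, mean, sd)), 0), 10)
}

# Self-report markers SR0-SR5 for one subject. Marker SRk reflects the state
# at that boundary; phase-boundary means follow the configured raw values.
simulate_self_reports <- function(subject_id, arm, config) {
  sr <- config$self_report
  phase_seq <- if (arm == "Relax-Stress") {
    c("arrival", "arrival", "Relaxation", "tRelaxed", "Stressor", "tStressed")
  } else {
    c("arrival", "arrival", "Stressor", "tStressed", "Relaxation", "tRelaxed")
  }
  means <- sr$marker_mean[phase_seq]
  stress <- rself_report(6, means, sr$sd)
  tension <- rself_report(6, pmax(means - 0.5, 0), sr$sd)
  concentration <- rself_report(6, 6, 1.2)
  data.frame(subject_id = subject_id, marker = paste0("SR", 0:5),
             stress = stress, tension = tension,
             concentration = concentration, stringsAsFactors = FALSE)
}

#' Simulate a complete two-arm study
#'
#' For every subject: an arm assignment (Relax-Stress or Stress-Relax),
#' self-reports at markers SR0-SR5, annotated trackpad event logs for the
#' tRelaxed and tStressed task phases (120 trials each, with gap artifacts
#' injected), and an EDA series per phase. Subject-level contact-area
#' baselines are shared across conditions so the configured paired condition
#' effect is realized. Fully reproducible from the config seed.
#'
#' @param config A [generator_config()].
#' @return An object of class `"study_dataset"`: list with `config`,
#'   `subjects` (per-subject list of `arm`, `self_reports` and per-condition
#'   `events`/`annotations`/`eda`), pooled `self_reports`, and `truth`.
#' @export
simulate_study <- function(config = generator_config()) {
  validate_generator_config(config)
  subjects <- vector("list", config$n_subjects)
  sr_all <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    arm <- config$arm_assignment[s]
    set.seed(derive_seed(config$seed, 300L, s))
    baseline <- rnorm(1, 0, config$area_model$between_sd)
    conds <- list()
    for (cond in condition_levels()) {
      sched <- generate_task_schedule(s, cond, config)
      set.seed(derive_seed(config$seed, 400L, s,
                           match(cond, condition_levels())))
      ev_list <- vector("list", nrow(sched))
      t_cursor <- 0
      t_start <- t_end <- numeric(nrow(sched))
      for (i in seq_len(nrow(sched))) {
        trial <- as.list(sched[i, ])
        trial$area_mean_mm2 <- config$area_model$mean[[cond]] + baseline
        ev <- simulate_stroke(trial, config, t0_s = t_cursor)
        ev <- inject_artifacts(ev, config)
        t_start[i] <- t_cursor
        t_end[i] <- max(ev$t_s) + 0.05
        t_cursor <- t_end[i] + 0.25
        ev_list[[i]] <- ev
      }
      events <- do.call(rbind, ev_list)
      rownames(events) <- NULL
      ann <- data.frame(trial_id = sched$trial_id, subject_id = s,
                        phase = cond, condition = cond,
                        task_type = sched$task_type,
                        distance_px = sched$distance_px,
                        width_px = sched$width_px,
                        t_start_s = t_start, t_end_s = t_end,
                        stringsAsFactors = FALSE)
      set.seed(derive_seed(config$seed, 500L, s,
                           match(cond, condition_levels())))
      eda <- simulate_eda(t_cursor, cond, config)
      conds[[cond]] <- list(events = events, annotations = ann, eda = eda)
    }
    set.seed(derive_seed(config$seed, 600L, s))
    sr <- simulate_self_reports(s, arm, config)
    sr_all[[s]] <- sr
    subjects[[s]] <- list(subject_id = s, arm = arm,
                          area_baseline_mm2 = baseline,
                          self_reports = sr, conditions = conds)
  }
  structure(list(config = config, subjects = subjects,
                 self_reports = do.call(rbind, sr_all),
                 truth = list(true_msd = config$true_msd,
                              area_model = config$area_model,
                              effect_spec = config$effect_spec)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  n_tr <- sum(vapply(x$subjects, function(s)
    sum(vapply(s$conditions, function(cc) nrow(cc$annotations), 0L)), 0L))
  cat(sprintf("Synthetic trackpad stress study: %d subjects, %d annotated trials\n",
              length(x$subjects), n_tr))
  invisible(x)
}
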