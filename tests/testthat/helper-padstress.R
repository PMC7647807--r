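# Shared fixtures and independent oracles, all built in code.

# Minimal well-formed event frame.
make_events <- function(t, x, finger = 1L, y = 35, major = 10, minor = 8) {
  n <- length(t)
  data.frame(t_s = t, finger_id = rep_len(as.integer(finger), n),
             x_mm = rep_len(x, n), y_mm = rep_len(y, n),
             major_mm = rep_len(major, n), minor_mm = rep_len(minor, n),
             state = rep("touching", n), pressed = rep(TRUE, n),
             stringsAsFactors = FALSE)
}

# A quiet generator: no jitter, no noise, no artifacts; sampling aligned to
# the default 10 ms fitting grid so resampling is the identity.
quiet_config <- function(zeta = 0.5, omega_d = 8, duration = 2,
                         seed = 1L, ...) {
  generator_config(
    sampling_mean_ms = 10, sampling_sd_ms = 0, position_noise_mm = 0,
    gap_probability = 0, stroke_duration_s = duration,
    true_msd = list(tRelaxed = list(zeta = zeta, omega_d = omega_d),
                    tStressed = list(zeta = zeta, omega_d = omega_d)),
    seed = seed, ...)
}

click_trial <- function(distance_px = 512, condition = "tRelaxed") {
  list(condition = condition, distance_px = distance_px, task_type = "click")
}

# Independent brute-force segmentation oracle: per finger, walks every
# consecutive pair and opens a new fragment whenever any cut condition
# holds; then filters by minimum length. Deliberately written as an O(n^2)
# scan, structurally unlike the vectorised implementation.
oracle_segment <- function(events, config) {
  frags <- list()
  discarded <- 0L
  for (fid in unique(events$finger_id)) {
    ev <- events[events$finger_id == fid, , drop = FALSE]
    ev <- ev[order(ev$t_s), , drop = FALSE]
    current <- 1L
    fragments <- list()
    if (nrow(ev) >= 2) {
      for (i in 2:nrow(ev)) {
        cut <- (ev$t_s[i] - ev$t_s[i - 1]) * 1000 > config$max_gap_ms ||
          abs(ev$x_mm[i] - ev$x_mm[i - 1]) > config$max_jump_mm ||
          abs(ev$y_mm[i] - ev$y_mm[i - 1]) > config$max_jump_mm
        if (cut) {
          fragments[[length(fragments) + 1L]] <- ev[current:(i - 1), , drop = FALSE]
          current <- i
        }
      }
    }
    fragments[[length(fragments) + 1L]] <- ev[current:nrow(ev), , drop = FALSE]
    for (fr in fragments) {
      if (nrow(fr) >= config$min_stroke_samples) {
        frags[[length(frags) + 1L]] <- fr
      } else discarded <- discarded + 1L
    }
  }
  list(strokes = frags, n_discarded = discarded)
}

# Random small trial with gaps, jumps and multiple fingers for the
# segmentation equivalence property.
random_trial_events <- function(n_events) {
  t <- cumsum(runif(n_events, 0.002, 0.12))
  x <- cumsum(rnorm(n_events, 0, 3))
  x <- pmin(pmax(70 + x, 0), 140)
  finger <- cumsum(c(1L, as.integer(runif(n_events - 1) < 0.08)))
  make_events(t, x, finger = finger, y = runif(1, 10, 60))
}

# Build an ar2_fit from known coefficients (poles of z^2 - a1 z - a2).
fit_ar2_coeffs <- function(a1, a2) {
  structure(list(a1 = a1, a2 = a2, poles = polyroot(c(-a2, -a1, 1))),
            class = "ar2_fit")
}

# Monte-Carlo oracle for paired t power: simulate standardized paired
# differences, count one-tailed rejections.
mc_power_paired_t <- function(dz, n, alpha = 0.05, reps = 4000) {
  mean(replicate(reps, {
    d <- rnorm(n, dz, 1)
    stats::t.test(d, alternative = "greater")$p.value < alpha
  }))
}
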