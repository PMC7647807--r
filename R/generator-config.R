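#' Canonical task configurations
#'
#' The study design crosses five target distances with four target widths for
#' each of the three task types (click, steer, drag-and-drop), giving 20
#' distance/width configurations per task type. Distances are shared across
#' task types; drag-and-drop uses a doubled width set because the dragged
#' object itself occupies space.
#'
#' @param task_type One of `"click"`, `"drag_and_drop"`, `"steer"`.
#' @return A data frame with columns `task_type`, `distance_px`, `width_px`
#'   (20 rows).
#' @export
#' @examples
#' nrow(task_configs("click"))  # 20
task_configs <- function(task_type = c("click", "drag_and_drop", "steer")) {
  task_type <- match.arg(task_type)
  distances <- c(64L, 128L, 256L, 512L, 1024L)
  widths <- if (task_type == "drag_and_drop") {
    c(16L, 32L, 64L, 128L)
  } else {
    c(8L, 16L, 32L, 64L)
  }
  out <- expand.grid(distance_px = distances, width_px = widths,
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(task_type = task_type, out, stringsAsFactors = FALSE)
}

task_type_levels <- function() c("click", "drag_and_drop", "steer")
condition_levels <- function() c("tRelaxed", "tStressed")

#' Synthetic-study generator configuration
#'
#' Bundles every tunable of the synthetic data generator: the logger's timing
#' model, the gap/artifact injection rate, the per-condition ground-truth
#' mass-spring-damper (MSD) parameters, the contact-area model, self-report
#' means, and the electrodermal activity (EDA) model. Defaults reproduce the
#' study conditions: 18 subjects split 8/10 across the two counterbalanced
#' arms, a mean inter-sample interval of 8.17 ms (SD 3.75), a 38% per-trial
#' gap probability, and contact areas anchored at 270.9 (relaxed) and
#' 284.6 mm^2 (stressed).
#'
#' @param n_subjects Number of subjects (>= 2; paired analyses need pairs).
#' @param arm_assignment Character vector of length `n_subjects` with values
#'   `"Relax-Stress"` or `"Stress-Relax"`; default splits 8/10 as in the
#'   study (subjects 1-8 in arm A).
#' @param sampling_mean_ms,sampling_sd_ms Mean and SD of the jittered
#'   inter-sample interval in milliseconds (truncated-normal, strictly
#'   positive).
#' @param gap_probability Per-trial probability of receiving at least one
#'   injected stroke discontinuity.
#' @param true_msd Named list with per-condition `zeta` (damping ratio, in
#'   (0,1)) and `omega_d` (damped frequency, rad/s).
#' @param area_model Named list: `mean` (per-condition mean contact area,
#'   mm^2), `between_sd` (between-subject SD of the subject baseline),
#'   `within_sd` (per-condition within-trial SD of per-sample areas),
#'   `aspect_meanlog`, `aspect_sdlog` (log aspect ratio of the contact
#'   ellipse, kept >= 1 so major >= minor).
#' @param effect_spec Optional named list of standardized condition effects.
#'   If `d_area_mean` is given, the stressed area mean is re-derived as
#'   relaxed mean + d * between_sd (overriding `area_model$mean[2]`).
#' @param eda_model Named list of per-condition EDA parameters: `tonic_uS`,
#'   `drift_uS_per_min`, `scr_rate_hz`, `amp_meanlog`, `amp_sdlog` (SCR
#'   amplitude lognormal, uS), `rise_s`, `decay_s` (biexponential shape),
#'   `noise_sd_uS`, and `sample_rate_hz`.
#' @param self_report Named list: `marker_mean` per-phase-boundary means on
#'   the 0-10 scale and `sd` of the truncated discretized normal.
#' @param stroke_duration_s Duration of each simulated trial's primary
#'   stroke, seconds.
#' @param position_noise_mm SD of additive positional noise on x.
#' @param px_to_mm Pixel-to-millimetre factor mapping screen-space target
#'   distance onto the 140 x 70 mm pad.
#' @param seed Integer seed; a fixed seed makes every generated dataset
#'   byte-identical.
#' @return An object of class `"generator_config"` (a validated list).
#' @export
generator_config <- function(n_subjects = 18L,
                             arm_assignment = NULL,
                             sampling_mean_ms = 8.17,
                             sampling_sd_ms = 3.75,
                             gap_probability = 0.38,
                             true_msd = list(
                               tRelaxed = list(zeta = 0.538, omega_d = 8.0),
                               tStressed = list(zeta = 0.540, omega_d = 8.2)
                             ),
                             area_model = list(
                               mean = c(tRelaxed = 270.9, tStressed = 284.6),
                               between_sd = 26.7,
                               within_sd = c(tRelaxed = 16.7, tStressed = 21.2),
                               aspect_meanlog = log(1.4),
                               aspect_sdlog = 0.08
                             ),
                             effect_spec = list(),
                             eda_model = list(
                               tonic_uS = c(tRelaxed = 2.06, tStressed = 4.22),
                               drift_uS_per_min = 0.05,
                               scr_rate_hz = c(tRelaxed = 0.10, tStressed = 0.17),
                               amp_meanlog = c(tRelaxed = log(0.15), tStressed = log(0.25)),
                               amp_sdlog = 0.4,
                               rise_s = 0.75,
                               decay_s = 3.0,
                               noise_sd_uS = 0.005,
                               sample_rate_hz = 4
                             ),
                             self_report = list(
                               marker_mean = c(arrival = 3.5, Relaxation = 2.27,
                                               tRelaxed = 3.78, Stressor = 6.22,
                                               tStressed = 4.50),
                               sd = 1.8
                             ),
                             stroke_duration_s = 2.0,
                             position_noise_mm = 0.05,
                             px_to_mm = 0.1,
                             seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.null(arm_assignment)) {
    arm_assignment <- rep(c("Relax-Stress", "Stress-Relax"),
                          c(ceiling(n_subjects * 8 / 18),
                            n_subjects - ceiling(n_subjects * 8 / 18)))
  }
  if (length(effect_spec$d_area_mean)) {
    area_model$mean[["tStressed"]] <-
      area_model$mean[["tRelaxed"]] +
      effect_spec$d_area_mean * area_model$between_sd
  }
  cfg <- structure(list(
    n_subjects = n_subjects, arm_assignment = arm_assignment,
    sampling_mean_ms = sampling_mean_ms, sampling_sd_ms = sampling_sd_ms,
    gap_probability = gap_probability, true_msd = true_msd,
    area_model = area_model, effect_spec = effect_spec,
    eda_model = eda_model, self_report = self_report,
    stroke_duration_s = stroke_duration_s,
    position_noise_mm = position_noise_mm,
    px_to_mm = px_to_mm, seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_subjects < 2L)
    stop("n_subjects must be >= 2: paired analyses are undefined for a single subject",
         call. = FALSE)
  if (length(cfg$arm_assignment) != cfg$n_subjects)
    stop("arm_assignment must have one entry per subject", call. = FALSE)
  if (!all(cfg$arm_assignment %in% c("Relax-Stress", "Stress-Relax")))
    stop("arm_assignment values must be 'Relax-Stress' or 'Stress-Relax'", call. = FALSE)
  if (cfg$gap_probability < 0 || cfg$gap_probability > 1)
    stop("gap_probability must lie in [0,1]", call. = FALSE)
  if (cfg$sampling_mean_ms <= 0 || cfg$sampling_sd_ms < 0)
    stop("sampling interval moments must be positive", call. = FALSE)
  if (cfg$stroke_duration_s <= 0)
    stop("stroke_duration_s must be positive", call. = FALSE)
  for (cond in condition_levels()) {
    msd <- cfg$true_msd[[cond]]
    if (is.null(msd) || msd$zeta <= 0 || msd$zeta >= 1)
      stop("true_msd zeta must lie in (0,1): the generator emits only underdamped strokes",
           call. = FALSE)
    if (msd$omega_d <= 0) stop("true_msd omega_d must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic study generator configuration\n")
  cat(sprintf("  subjects: %d (%d Relax-Stress / %d Stress-Relax)\n",
              x$n_subjects, sum(x$arm_assignment == "Relax-Stress"),
              sum(x$arm_assignment == "Stress-Relax")))
  cat(sprintf("  sampling: %.2f ms (SD %.2f); gap probability %.2f\n",
              x$sampling_mean_ms, x$sampling_sd_ms, x$gap_probability))
  cat(sprintf("  true MSD: relaxed zeta=%.3f omega=%.1f, stressed zeta=%.3f omega=%.1f rad/s\n",
              x$true_msd$tRelaxed$zeta, x$true_msd$tRelaxed$omega_d,
              x$true_msd$tStressed$zeta, x$true_msd$tStressed$omega_d))
  cat(sprintf("  contact area: %.1f / %.1f mm^2; seed %d\n",
              x$area_model$mean[["tRelaxed"]], x$area_model$mean[["tStressed"]],
              x$seed))
  invisible(x)
}
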