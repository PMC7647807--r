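# Finger-dynamics metrics: contact area, velocity and acceleration per
# stroke, aggregated to trials, phases, and the mixed-task level.

#' Contact area of the fingertip ellipse
#'
#' Computed literally as `pi * a * b` from the logger's major/minor axis
#' values. If the logger reports full axes rather than semi-axes the true
#' ellipse area is a quarter of this; set `axes_are_full = TRUE` to apply
#' the /4 factor. The default keeps the literal product, the convention the
#' downstream statistics are anchored to.
#'
#' @param major_mm,minor_mm Ellipse axes, mm (`major >= minor >= 0`).
#' @param axes_are_full Treat inputs as full axes (divide by 4).
#' @return Area in mm^2 (vectorised).
#' @export
#' @examples
#' contact_area(10, 5)  # 157.0796
contact_area <- function(major_mm, minor_mm, axes_are_full = FALSE) {
  if (any(minor_mm < 0) || any(major_mm < 0))
    stop("ellipse axes must be non-negative", call. = FALSE)
  if (any(major_mm < minor_mm))
    stop("major axis must be >= minor axis", call. = FALSE)
  a <- pi * major_mm * minor_mm
  if (axes_are_full) a / 4 else a
}

#' Velocity and acceleration series of a stroke
#'
#' Finger velocity is the finite difference of the horizontal position and
#' acceleration the finite difference of velocity (signed, x-direction
#' only): `v[i] = (x[i+1]-x[i])/(t[i+1]-t[i])`, and likewise for `a` on `v`.
#'
#' @param stroke Stroke data frame (`t_s`, `x_mm`, >= 3 events,
#'   strictly increasing times).
#' @return List with `velocity_mm_s` (length n-1), `accel_mm_s2` (length
#'   n-2), and the midpoint time grids `t_v`, `t_a`.
#' @export
stroke_kinematics <- function(stroke) {
  n <- nrow(stroke)
  if (n < 3) stop("need at least 3 events for kinematics", call. = FALSE)
  dt <- diff(stroke$t_s)
  if (any(dt < 0)) stop("events must be time-sorted", call. = FALSE)
  dup <- which(dt == 0)
  if (length(dup))
    stop(sprintf("duplicate timestamps at rows %d and %d",
                 dup[1], dup[1] + 1L), call. = FALSE)
  v <- diff(stroke$x_mm) / dt
  t_v <- stroke$t_s[-n]
  a <- diff(v) / diff(t_v)
  list(velocity_mm_s = v, accel_mm_s2 = a,
       t_v = t_v, t_a = t_v[-length(t_v)])
}

# Mean/SD of one stroke's area, velocity, acceleration samples.
stroke_metrics <- function(stroke, axes_are_full = FALSE) {
  kin <- stroke_kinematics(stroke)
  area <- contact_area(stroke$major_mm, stroke$minor_mm, axes_are_full)
  c(mean_area_mm2 = mean(area), sd_area_mm2 = stats::sd(area),
    mean_velocity_mm_s = mean(kin$velocity_mm_s),
    sd_velocity_mm_s = stats::sd(kin$velocity_mm_s),
    mean_accel_mm_s2 = mean(kin$accel_mm_s2),
    sd_accel_mm_s2 = stats::sd(kin$accel_mm_s2))
}

#' Per-trial finger-dynamics metrics
#'
#' All strokes and substrokes of the trial are kept; each stroke's mean and
#' SD of contact area (over every sample), velocity and acceleration are
#' computed, and the trial value is the unweighted mean of the per-stroke
#' values. Strokes with fewer than 3 events are skipped.
#'
#' @param trial_strokes Stroke list from [split_strokes()].
#' @param axes_are_full See [contact_area()].
#' @return One-row data frame with the six metric columns plus
#'   `n_strokes_used`; all-NA (flagged absent) if no stroke is usable.
#' @export
trial_metrics <- function(trial_strokes, axes_are_full = FALSE) {
  usable <- Filter(function(s) nrow(s) >= 3, trial_strokes)
  if (length(usable) == 0) {
    out <- as.data.frame(as.list(rep(NA_real_, 6)))
    names(out) <- c("mean_area_mm2", "sd_area_mm2", "mean_velocity_mm_s",
                    "sd_velocity_mm_s", "mean_accel_mm_s2", "sd_accel_mm_s2")
    out$n_strokes_used <- 0L
    return(out)
  }
  m <- t(vapply(usable, stroke_metrics, numeric(6),
                axes_are_full = axes_are_full))
  out <- as.data.frame(as.list(colMeans(m)))
  out$n_strokes_used <- length(usable)
  out
}

metric_columns <- function() {
  c("mean_area_mm2", "sd_area_mm2", "mean_velocity_mm_s",
    "sd_velocity_mm_s", "mean_accel_mm_s2", "sd_accel_mm_s2")
}

#' Aggregate trial metrics to phase level
#'
#' Two-stage averaging, as the mixed-task protocol prescribes: per-task-type
#' values are the mean over that type's valid trials (all configurations
#' and repetitions), and the mixed-task value is the unweighted mean of the
#' three per-task-type values — not the pooled trial mean, so unequal
#' valid-trial counts across task types do not bias the aggregate.
#'
#' @param trials Data frame with `task_type` plus the six metric columns
#'   (one row per trial, for one subject and condition). Rows with NA
#'   metrics (flagged-absent trials) are dropped.
#' @param level `"mixed_task"` (default) or `"per_task_type"`.
#' @return For `"per_task_type"`, a data frame with one row per task type;
#'   for `"mixed_task"`, a one-row data frame of the six metrics.
#' @export
aggregate_phase <- function(trials, level = c("mixed_task", "per_task_type")) {
  level <- match.arg(level)
  cols <- metric_columns()
  valid <- stats::complete.cases(trials[, cols])
  trials <- trials[valid, , drop = FALSE]
  types <- task_type_levels()
  per_type <- lapply(types, function(tt) {
    sub <- trials[trials$task_type == tt, cols, drop = FALSE]
    if (nrow(sub) == 0)
      stop(sprintf("task type '%s' has no valid trials: cannot form the mixed-task value", tt),
           call. = FALSE)
    colMeans(sub)
  })
  per_type_df <- cbind(data.frame(task_type = types, stringsAsFactors = FALSE),
                       as.data.frame(do.call(rbind, per_type)))
  if (level == "per_task_type") return(per_type_df)
  as.data.frame(as.list(colMeans(per_type_df[, cols])))
}
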