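# Stroke segmentation: split each trial's events into contiguous
# single-finger strokes, detect gaps, and select the largest continuous
# stroke (the one carrying the trial's displacement information).

#' Segmentation configuration
#'
#' @param max_gap_ms Maximum inter-sample interval within a stroke, ms
#'   (default 50, about six times the logger's mean sampling interval).
#' @param max_jump_mm Maximum per-sample coordinate jump in x or y, mm
#'   (default 20). The threshold must exceed what continuous task motion can
#'   cover between consecutive samples — peak stroke velocities reach
#'   ~600 mm/s, i.e. ~12 mm across a late jittered interval — while
#'   lift-and-replace discontinuities show far larger jumps or trip the time
#'   rule.
#' @param min_stroke_samples Minimum events per retained stroke; shorter
#'   fragments are discarded (and counted).
#' @return A list of class `"segmentation_config"`.
#' @export
segmentation_config <- function(max_gap_ms = 50, max_jump_mm = 20,
                                min_stroke_samples = 4L) {
  stopifnot(max_gap_ms > 0, max_jump_mm > 0, min_stroke_samples > 0)
  structure(list(max_gap_ms = max_gap_ms, max_jump_mm = max_jump_mm,
                 min_stroke_samples = as.integer(min_stroke_samples)),
            class = "segmentation_config")
}

#' Split a trial's events into contiguous single-finger strokes
#'
#' Events are partitioned by `finger_id` and cut wherever the inter-sample
#' interval exceeds `max_gap_ms` or the coordinate jump in x or y exceeds
#' `max_jump_mm` (large variations in x or y mark gaps). Fragments shorter
#' than `min_stroke_samples` are discarded and counted. Concurrent traces
#' from different fingers yield separate, possibly time-overlapping strokes.
#'
#' @param trial_events Time-sorted event data frame for one trial.
#' @param config A [segmentation_config()].
#' @return A list of stroke data frames (attribute `"n_discarded"` holds the
#'   count of discarded fragments, `"n_discarded_events"` their event count),
#'   each with attributes `finger_id`, `t_span` and `x_extent_mm`.
#' @export
split_strokes <- function(trial_events, config = segmentation_config()) {
  if (is.null(trial_events) || nrow(trial_events) == 0) {
    out <- list()
    attr(out, "n_discarded") <- 0L
    attr(out, "n_discarded_events") <- 0L
    return(out)
  }
  strokes <- list()
  n_disc <- 0L
  n_disc_ev <- 0L
  for (fid in unique(trial_events$finger_id)) {
    ev <- trial_events[trial_events$finger_id == fid, , drop = FALSE]
    ev <- ev[order(ev$t_s), , drop = FALSE]
    if (nrow(ev) == 1) {
      cut_after <- integer(0)
    } else {
      dt <- diff(ev$t_s) * 1000
      dx <- abs(diff(ev$x_mm))
      dy <- abs(diff(ev$y_mm))
      cut_after <- which(dt > config$max_gap_ms | dx > config$max_jump_mm |
                           dy > config$max_jump_mm)
    }
    grp <- cumsum(c(1L, as.integer(seq_len(nrow(ev) - 1) %in% cut_after)))
    for (g in unique(grp)) {
      frag <- ev[grp == g, , drop = FALSE]
      if (nrow(frag) >= config$min_stroke_samples) {
        rownames(frag) <- NULL
        attr(frag, "finger_id") <- fid
        attr(frag, "t_span") <- max(frag$t_s) - min(frag$t_s)
        attr(frag, "x_extent_mm") <- abs(frag$x_mm[nrow(frag)] - frag$x_mm[1])
        strokes[[length(strokes) + 1L]] <- frag
      } else {
        n_disc <- n_disc + 1L
        n_disc_ev <- n_disc_ev + nrow(frag)
      }
    }
  }
  # deterministic order: by start time, then finger id
  if (length(strokes)) {
    ord <- order(vapply(strokes, function(s) s$t_s[1], 0),
                 vapply(strokes, function(s) attr(s, "finger_id"), 0))
    strokes <- strokes[ord]
  }
  attr(strokes, "n_discarded") <- n_disc
  attr(strokes, "n_discarded_events") <- n_disc_ev
  strokes
}

#' Net horizontal extent of a stroke
#' @param stroke A stroke data frame.
#' @return `|x_end - x_start|` in mm.
#' @export
stroke_x_extent <- function(stroke) {
  abs(stroke$x_mm[nrow(stroke)] - stroke$x_mm[1])
}

#' Select the largest continuous stroke of a trial
#'
#' "Largest" is the net horizontal extent `|x_end - x_start|`: the tasks are
#' horizontal, so x carries the displacement information. Ties are broken by
#' the longer time span, then by the earlier start (deterministic).
#'
#' @param strokes List of strokes from [split_strokes()].
#' @return The selected stroke data frame.
#' @export
select_largest_stroke <- function(strokes) {
  if (length(strokes) == 0) stop("no valid stroke", call. = FALSE)
  ext <- vapply(strokes, stroke_x_extent, 0)
  span <- vapply(strokes, function(s) max(s$t_s) - min(s$t_s), 0)
  start <- vapply(strokes, function(s) s$t_s[1], 0)
  ord <- order(-ext, -span, start)
  strokes[[ord[1]]]
}

#' Per-subject fraction of trials with at least one gap
#'
#' A trial "has a gap" iff segmentation produced more than one stroke or
#' discarded any fragment — i.e. its events did not form a single continuous
#' single-finger stroke.
#'
#' @param trial_strokes A list (one element per trial) of stroke lists as
#'   returned by [split_strokes()].
#' @return The fraction of trials with a gap, in `[0, 1]`.
#' @export
gap_statistics <- function(trial_strokes) {
  if (length(trial_strokes) == 0) stop("zero trials", call. = FALSE)
  has_gap <- vapply(trial_strokes, function(st) {
    length(st) > 1 || (attr(st, "n_discarded") %||% 0L) > 0L
  }, NA)
  mean(has_gap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export strokes as a flat summary table
#'
#' @param trial_strokes Named list (by trial id) of stroke lists.
#' @return Data frame with one row per stroke: `trial_id`, `stroke_index`,
#'   `finger_id`, `n_events`, `t_start_s`, `t_end_s`, `x_extent_mm`.
#' @export
strokes_summary <- function(trial_strokes) {
  rows <- list()
  for (tid in names(trial_strokes)) {
    st <- trial_strokes[[tid]]
    for (i in seq_along(st)) {
      s <- st[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tid, stroke_index = i,
        finger_id = attr(s, "finger_id"),
        n_events = nrow(s), t_start_s = min(s$t_s), t_end_s = max(s$t_s),
        x_extent_mm = stroke_x_extent(s), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
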