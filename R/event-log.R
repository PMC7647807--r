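# Event-log CSV dialect: the plain-text stand-in for the study's trackpad
# logger. Events CSV columns: t_s,finger_id,x_mm,y_mm,major_mm,minor_mm,
# state,pressed; annotations CSV columns: trial_id,subject_id,phase,
# condition,task_type,distance_px,width_px,t_start_s,t_end_s.

event_log_columns <- function() {
  c("t_s", "finger_id", "x_mm", "y_mm", "major_mm", "minor_mm",
    "state", "pressed")
}
annotation_columns <- function() {
  c("trial_id", "subject_id", "phase", "condition", "task_type",
    "distance_px", "width_px", "t_start_s", "t_end_s")
}

#' Validate touch events against the logger invariants
#'
#' Checks that the ellipse major axis is at least the minor axis, both are
#' non-negative, coordinates fall inside the 140 x 70 mm pad, and times are
#' finite. All offending row numbers are reported together.
#'
#' @param events Event data frame (see [read_event_log()] for the columns).
#' @return Invisibly `events`; errors listing offending rows otherwise.
#' @export
validate_events <- function(events) {
  missing <- setdiff(event_log_columns(), names(events))
  if (length(missing))
    stop("events missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  bad <- list(
    "major_mm < minor_mm" = which(events$major_mm < events$minor_mm),
    "negative axis" = which(events$minor_mm < 0),
    "x out of pad bounds [0,140]" = which(events$x_mm < 0 | events$x_mm > 140),
    "y out of pad bounds [0,70]" = which(events$y_mm < 0 | events$y_mm > 70),
    "non-finite time" = which(!is.finite(events$t_s))
  )
  bad <- bad[lengths(bad) > 0]
  if (length(bad)) {
    msg <- vapply(names(bad), function(nm)
      sprintf("%s at rows %s", nm,
              paste(utils::head(bad[[nm]], 10), collapse = ",")), "")
    stop("invalid events: ", paste(msg, collapse = "; "), call. = FALSE)
  }
  invisible(events)
}

#' Write an event log and trial annotations to CSV
#'
#' Serializes with the logger's stated precision: coordinates and ellipse
#' axes to exactly 2 decimals (hundredth of a millimetre, round-half-even),
#' times to 6 decimals. Round-trips losslessly at that precision.
#'
#' @param events Event data frame satisfying [validate_events()].
#' @param annotations Trial annotation data frame (may be `NULL`).
#' @param dir Destination directory (created if needed).
#' @param prefix File name prefix; files are `<prefix>_events.csv` and
#'   `<prefix>_annotations.csv`.
#' @return Invisibly, the named character vector of paths written.
#' @export
write_event_log <- function(events, annotations = NULL, dir, prefix = "log") {
  validate_events(events)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- data.frame(
    t_s = sprintf("%.6f", events$t_s),
    finger_id = as.integer(events$finger_id),
    x_mm = sprintf("%.2f", round(events$x_mm, 2)),
    y_mm = sprintf("%.2f", round(events$y_mm, 2)),
    major_mm = sprintf("%.2f", round(events$major_mm, 2)),
    minor_mm = sprintf("%.2f", round(events$minor_mm, 2)),
    state = as.character(events$state),
    pressed = as.logical(events$pressed),
    stringsAsFactors = FALSE
  )
  ev_path <- file.path(dir, paste0(prefix, "_events.csv"))
  utils::write.csv(ev, ev_path, row.names = FALSE, quote = FALSE)
  paths <- c(events = ev_path)
  if (!is.null(annotations)) {
    an_path <- file.path(dir, paste0(prefix, "_annotations.csv"))
    an <- annotations[, annotation_columns()]
    # windows share the event clock's microsecond serialization so rounding
    # cannot push a boundary event outside its trial
    an$t_start_s <- sprintf("%.6f", an$t_start_s)
    an$t_end_s <- sprintf("%.6f", an$t_end_s)
    utils::write.csv(an, an_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, annotations = an_path)
  }
  invisible(paths)
}

#' Read an event log (and optional annotations) from CSV
#'
#' Parses the dialect written by [write_event_log()], returning typed
#' records. Per-finger time monotonicity and the ellipse-axis invariant are
#' enforced with errors naming the offending rows; events whose times fall
#' outside every annotated trial window trigger a warning but are retained.
#'
#' @param events_path Path to the events CSV.
#' @param annotations_path Optional path to the annotations CSV.
#' @return A list with `events` and `annotations` (`NULL` if not supplied).
#' @export
read_event_log <- function(events_path, annotations_path = NULL) {
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        colClasses = c(
                          t_s = "numeric", finger_id = "integer",
                          x_mm = "numeric", y_mm = "numeric",
                          major_mm = "numeric", minor_mm = "numeric",
                          state = "character", pressed = "logical"))
  unknown <- setdiff(names(ev), event_log_columns())
  if (length(unknown))
    stop("unknown event columns: ", paste(unknown, collapse = ", "), call. = FALSE)
  validate_events(ev)
  for (fid in unique(ev$finger_id)) {
    idx <- which(ev$finger_id == fid)
    dt <- diff(ev$t_s[idx])
    if (any(dt < 0))
      stop(sprintf("non-monotone time for finger %d at row %d",
                   fid, idx[which(dt < 0)[1] + 1]), call. = FALSE)
  }
  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
    missing <- setdiff(annotation_columns(), names(ann))
    if (length(missing))
      stop("annotations missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(ann$t_start_s >= ann$t_end_s))
      stop("annotation windows must satisfy t_start < t_end", call. = FALSE)
    covered <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(ann)))
      covered <- covered | (ev$t_s >= ann$t_start_s[i] & ev$t_s < ann$t_end_s[i])
    if (any(!covered))
      warning(sprintf("%d event(s) fall outside all annotated trial windows; retained unassigned",
                      sum(!covered)), call. = FALSE)
  }
  list(events = ev, annotations = ann)
}

#' Assign events to trials by annotation windows
#'
#' Each event is assigned to the unique trial whose half-open window
#' `[t_start, t_end)` contains its timestamp; an event at exactly `t_end`
#' belongs to the next trial. Events outside every window are dropped and
#' counted.
#'
#' @param events Event data frame.
#' @param annotations Annotation data frame with non-overlapping windows
#'   (per subject).
#' @return A named list of event data frames, one per `trial_id`, with an
#'   attribute `"n_unassigned"` giving the dropped-event count.
#' @export
assign_events_to_trials <- function(events, annotations) {
  ann <- annotations[order(annotations$t_start_s), , drop = FALSE]
  if (nrow(ann) > 1 &&
      any(ann$t_start_s[-1] < ann$t_end_s[-nrow(ann)]))
    stop("overlapping trial windows", call. = FALSE)
  idx <- findInterval(events$t_s, ann$t_start_s)
  inside <- idx >= 1 & events$t_s < ann$t_end_s[pmax(idx, 1)]
  out <- vector("list", nrow(ann))
  names(out) <- ann$trial_id
  for (i in seq_len(nrow(ann))) {
    sel <- inside & idx == i
    tr <- events[sel, , drop = FALSE]
    rownames(tr) <- NULL
    out[[i]] <- tr
  }
  attr(out, "n_unassigned") <- sum(!inside)
  out
}
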