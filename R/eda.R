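# Electrodermal activity processing: low-pass filtering, rule-based quality
# screening, tonic/phasic decomposition, SCR counting and per-phase
# summaries. Validates physiologically that the stressor worked.

as_eda_series <- function(x) {
  if (inherits(x, "eda_series")) return(x)
  stopifnot(is.list(x), !is.null(x$t_s), !is.null(x$eda_uS))
  if (is.null(x$sample_rate_hz))
    x$sample_rate_hz <- 1 / stats::median(diff(x$t_s))
  structure(x, class = "eda_series")
}

#' Low-pass filter an EDA series
#'
#' Applies a 6th-order Butterworth low-pass at `cutoff_hz` (default 1 Hz).
#' Filtering is zero-phase (forward-backward) so SCR peak latencies are not
#' shifted. Length is preserved.
#'
#' @param series An `eda_series` (or list with `t_s`, `eda_uS`,
#'   `sample_rate_hz`).
#' @param cutoff_hz Cutoff frequency, Hz.
#' @return The filtered `eda_series`.
#' @export
filter_eda <- function(series, cutoff_hz = 1) {
  series <- as_eda_series(series)
  fs <- series$sample_rate_hz
  if (fs <= 2 * cutoff_hz)
    stop("sample rate must exceed twice the cutoff frequency", call. = FALSE)
  bf <- signal::butter(6, cutoff_hz / (fs / 2), type = "low")
  x <- series$eda_uS
  n <- length(x)
  # demean + odd reflection padding so the forward-backward pass has no
  # edge transients (a DC-constant series passes through exactly)
  m <- mean(x)
  x <- x - m
  np <- min(n - 1, max(12L, as.integer(3 * fs / cutoff_hz)))
  pad <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, pad))
  series$eda_uS <- y[(np + 1):(np + n)] + m
  series$filtered <- TRUE
  series
}

#' Rule-based EDA quality screen
#'
#' Flags a recording for exclusion if (a) it carries no signal (range below
#' 0.01 uS), (b) any sample exceeds 20 uS (anomalous signal), or (c) more
#' than 5% of its 5-second epochs are noisy. An epoch is noisy when any
#' sample-to-sample jump exceeds `jump_uS` or any value leaves
#' `[0.01, 20]` uS — a deterministic stand-in for learned artifact
#' classifiers.
#'
#' @param series An `eda_series`.
#' @param epoch_s Epoch length, seconds.
#' @param max_noisy_fraction Exclusion threshold on the noisy-epoch fraction.
#' @param jump_uS Maximum plausible sample-to-sample jump, uS.
#' @return A list of class `"eda_quality_report"`: `excluded`, `reasons`
#'   (subset of `no_signal`, `above_20uS`, `noisy_epochs_gt_5pct`),
#'   `noisy_epoch_fraction`.
#' @export
screen_quality <- function(series, epoch_s = 5, max_noisy_fraction = 0.05,
                           jump_uS = 1) {
  series <- as_eda_series(series)
  x <- series$eda_uS
  fs <- series$sample_rate_hz
  reasons <- character(0)
  if (diff(range(x)) < 0.01) reasons <- c(reasons, "no_signal")
  if (any(x > 20)) reasons <- c(reasons, "above_20uS")
  per_epoch <- max(1L, as.integer(round(epoch_s * fs)))
  n_epochs <- max(1L, floor(length(x) / per_epoch))
  noisy <- vapply(seq_len(n_epochs), function(i) {
    seg <- x[((i - 1) * per_epoch + 1):(i * per_epoch)]
    any(abs(diff(seg)) > jump_uS) || any(seg < 0.01 | seg > 20)
  }, NA)
  frac <- mean(noisy)
  if (frac > max_noisy_fraction) reasons <- c(reasons, "noisy_epochs_gt_5pct")
  structure(list(excluded = length(reasons) > 0, reasons = reasons,
                 noisy_epoch_fraction = frac),
            class = "eda_quality_report")
}

#' Decompose EDA into tonic and phasic components
#'
#' The tonic (baseline) component is a sliding-window low-percentile
#' envelope: the 10th percentile over a 10 s centred window, smoothed by a
#' 1 s moving average. The phasic component is the series minus the tonic,
#' floored at zero; the unfloored phasic plus the tonic reconstructs the
#' input exactly. The baseline is invariant to constant offsets, so phasic
#' amplitudes do not depend on the tonic level.
#'
#' @param series A filtered `eda_series`.
#' @param window_s Percentile window, seconds.
#' @param probs Baseline percentile (0-1).
#' @param smooth_s Moving-average smoothing, seconds.
#' @return List with `tonic`, `phasic` (floored), `phasic_unfloored`, and
#'   the input `series`.
#' @export
decompose_eda <- function(series, window_s = 10, probs = 0.10, smooth_s = 1) {
  series <- as_eda_series(series)
  x <- series$eda_uS
  fs <- series$sample_rate_hz
  w <- as.integer(round(window_s * fs))
  if (length(x) < w) stop("series shorter than the baseline window", call. = FALSE)
  half <- w %/% 2
  n <- length(x)
  tonic <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs, names = FALSE, type = 7)
  }, 0)
  k <- max(1L, as.integer(round(smooth_s * fs)))
  if (k > 1) {
    pre <- k %/% 2
    pad <- c(rep(tonic[1], pre), tonic, rep(tonic[n], k - 1L - pre))
    cs <- c(0, cumsum(pad))
    tonic <- (cs[seq_len(n) + k] - cs[seq_len(n)]) / k
  }
  phasic_un <- x - tonic
  list(tonic = tonic, phasic = pmax(phasic_un, 0),
       phasic_unfloored = phasic_un, series = series)
}

#' Count skin conductance responses in a phasic signal
#'
#' Counts local maxima whose prominence above the preceding trough is at
#' least `min_amplitude_uS` (default 0.01 uS), with a minimum inter-peak
#' separation of `min_separation_s`. The phasic driver is smoothed by a
#' short moving average first (`smooth_s`, default 1 s): SCR pulses are
#' several seconds wide so they pass intact, while single-sample noise
#' bumps that would otherwise clear the prominence threshold are
#' suppressed. The count is monotone non-increasing in the amplitude
#' threshold.
#'
#' @param phasic Non-negative phasic signal.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param min_amplitude_uS Amplitude (prominence) threshold, uS.
#' @param min_separation_s Minimum separation between counted peaks, s.
#' @param smooth_s Moving-average width applied before peak picking, s
#'   (0 disables).
#' @return List with `count` and `peak_idx` (indices of counted peaks).
#' @export
count_scrs <- function(phasic, sample_rate_hz, min_amplitude_uS = 0.01,
                       min_separation_s = 1, smooth_s = 1) {
  n <- length(phasic)
  if (n < 3) return(list(count = 0L, peak_idx = integer(0)))
  k <- max(1L, as.integer(round(smooth_s * sample_rate_hz)))
  if (k > 1) {
    pre <- k %/% 2
    pad <- c(rep(phasic[1], pre), phasic, rep(phasic[n], k - 1L - pre))
    cs <- c(0, cumsum(pad))
    phasic <- (cs[seq_len(n) + k] - cs[seq_len(n)]) / k
  }
  d <- diff(phasic)
  # local maxima: rising before, falling after (plateaus take the first index)
  is_peak <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(is_peak)) return(list(count = 0L, peak_idx = integer(0)))
  # prominence above the preceding trough
  keep <- logical(length(is_peak))
  last_trough_min <- phasic[1]
  prev <- 1L
  for (j in seq_along(is_peak)) {
    i <- is_peak[j]
    trough <- min(phasic[prev:i])
    keep[j] <- (phasic[i] - trough) >= min_amplitude_uS
    prev <- i
  }
  peaks <- is_peak[keep]
  if (length(peaks) > 1) {
    # greedy left-to-right spacing: optimal for 1-D selection, and the count
    # is monotone non-increasing when candidates are removed (threshold up)
    min_gap <- min_separation_s * sample_rate_hz
    sel <- peaks[1]
    for (p in peaks[-1])
      if (p - sel[length(sel)] >= min_gap) sel <- c(sel, p)
    peaks <- sel
  }
  list(count = length(peaks), peak_idx = peaks)
}

#' Per-phase EDA summary
#'
#' Filters, decomposes and summarizes the recording within each annotated
#' phase window, reporting the tonic mean, phasic mean and SCR count. Only
#' the tRelaxed and tStressed task phases are summarized.
#'
#' @param series An `eda_series` (raw; filtering is applied here).
#' @param phase_windows Data frame with `phase`, `t_start_s`, `t_end_s`.
#' @param min_amplitude_uS SCR amplitude threshold, uS.
#' @return Data frame with one row per phase: `phase`, `tonic_mean_uS`,
#'   `phasic_mean_uS`, `scr_count`, `duration_s`.
#' @export
eda_phase_summary <- function(series, phase_windows, min_amplitude_uS = 0.01) {
  series <- as_eda_series(series)
  filt <- filter_eda(series)
  keep <- phase_windows$phase %in% condition_levels()
  pw <- phase_windows[keep, , drop = FALSE]
  if (nrow(pw) == 0) stop("no tRelaxed/tStressed phase windows", call. = FALSE)
  rows <- lapply(seq_len(nrow(pw)), function(i) {
    sel <- filt$t_s >= pw$t_start_s[i] & filt$t_s < pw$t_end_s[i]
    if (!any(sel)) stop(sprintf("empty phase window '%s'", pw$phase[i]), call. = FALSE)
    sub <- structure(list(t_s = filt$t_s[sel], eda_uS = filt$eda_uS[sel],
                          sample_rate_hz = filt$sample_rate_hz),
                     class = "eda_series")
    dec <- decompose_eda(sub)
    scr <- count_scrs(dec$phasic, sub$sample_rate_hz, min_amplitude_uS)
    data.frame(phase = pw$phase[i],
               tonic_mean_uS = mean(dec$tonic),
               phasic_mean_uS = mean(dec$phasic),
               scr_count = scr$count,
               duration_s = pw$t_end_s[i] - pw$t_start_s[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
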