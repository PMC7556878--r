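# Locomotion segmentation and locomotion-triggered analysis: binarization
# of the treadmill velocity signal, stationary-period and event extraction,
# triggered averaging, evoked amplitude, onset time, and the
# locomotion-induced dilation metric.

#' Binarize a treadmill velocity trace into moving / stationary
#'
#' The velocity signal is zero-phase low-pass filtered (10 Hz, fifth-order
#' Butterworth), the acceleration is taken as the central difference, and
#' samples where |acceleration| exceeds `accel_threshold` are labeled
#' moving. The threshold is applied in cm/s^2 regardless of sample rate;
#' because its effective sensitivity depends on the encoder rate it is
#' exposed as configuration.
#'
#' @param trace a `locomotion_trace` (velocity in cm/s) or numeric vector.
#' @param sample_rate Hz (taken from the trace when available); must
#'   exceed 20 Hz for the 10 Hz filter to be valid.
#' @param accel_threshold cm/s^2 (default 1e-5).
#' @param lowpass_hz,filter_order filter parameters (defaults 10 Hz,
#'   order 5).
#' @return logical vector, TRUE = moving.
#' @export
binarize_locomotion <- function(trace, sample_rate = NULL,
                                accel_threshold = 1e-5, lowpass_hz = 10,
                                filter_order = 5) {
  if (inherits(trace, "locomotion_trace")) {
    v <- trace$velocity
    sample_rate <- sample_rate %||% trace$sample_rate
  } else {
    v <- as.numeric(trace)
    if (is.null(sample_rate)) stop_invalid("sample_rate required")
  }
  if (sample_rate <= 2 * lowpass_hz)
    stop_invalid("invalid-rate: sample_rate must exceed ", 2 * lowpass_hz,
                 " Hz")
  vf <- butter_filtfilt(v, sample_rate, high = lowpass_hz,
                        order = filter_order)
  n <- length(vf)
  acc <- numeric(n)
  acc[2:(n - 1)] <- (vf[3:n] - vf[1:(n - 2)]) * sample_rate / 2
  acc[1] <- (vf[2] - vf[1]) * sample_rate
  acc[n] <- (vf[n] - vf[n - 1]) * sample_rate
  abs(acc) > accel_threshold
}

# merge moving runs separated by < merge_gap_s of stillness
merge_moving_runs <- function(moving, sample_rate, merge_gap_s) {
  runs <- logical_runs(moving)
  if (nrow(runs) < 2) return(runs)
  gap <- (runs[-1, "start"] - runs[-nrow(runs), "end"] - 1) / sample_rate
  keep_sep <- gap >= merge_gap_s
  grp <- cumsum(c(TRUE, keep_sep))
  t(vapply(split(seq_len(nrow(runs)), grp), function(ix) {
    c(start = runs[ix[1], "start"], end = runs[ix[length(ix)], "end"])
  }, c(start = 0, end = 0)))
}

#' Locomotion events as merged moving intervals
#'
#' Moving runs separated by less than `merge_gap_s` of stillness are
#' merged into one event (encoder jitter otherwise splits bouts); events
#' are reported as (onset, offset) in seconds, onsets aligned to the first
#' moving sample.
#'
#' @param moving logical mask from [binarize_locomotion()].
#' @param sample_rate Hz.
#' @param merge_gap_s merge gap, s (default 1).
#' @return matrix with columns `onset_s`, `offset_s`.
#' @export
locomotion_events <- function(moving, sample_rate, merge_gap_s = 1) {
  runs <- merge_moving_runs(moving, sample_rate, merge_gap_s)
  if (nrow(runs) == 0)
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("onset_s", "offset_s"))))
  out <- cbind(onset_s = (runs[, "start"] - 1) / sample_rate,
               offset_s = (runs[, "end"] - 1) / sample_rate)
  rownames(out) <- NULL
  out
}

#' Stationary periods with post- and pre-event buffers
#'
#' Maximal still intervals, trimmed by `post_buffer_s` (default 2 s) after
#' the end of any preceding locomotion event and by `pre_buffer_s`
#' (default 1 s) before the start of the next event; intervals shorter
#' than `min_duration_s` are dropped. An interval at the trace start has
#' no leading trim, one at the end no trailing trim.
#'
#' @param moving logical mask.
#' @param sample_rate Hz.
#' @param min_duration_s minimum retained duration, s (default 1).
#' @param post_buffer_s,pre_buffer_s buffers, s.
#' @param merge_gap_s event merge gap passed to [locomotion_events()].
#' @return matrix with columns `start_s`, `end_s`.
#' @export
find_stationary_periods <- function(moving, sample_rate, min_duration_s = 1,
                                    post_buffer_s = 2, pre_buffer_s = 1,
                                    merge_gap_s = 1) {
  n <- length(moving)
  ev <- locomotion_events(moving, sample_rate, merge_gap_s)
  dur <- (n - 1) / sample_rate
  if (nrow(ev) == 0) {
    per <- matrix(c(0, dur), 1, 2)
  } else {
    starts <- c(0, ev[, "offset_s"] + post_buffer_s)
    ends <- c(ev[, "onset_s"] - pre_buffer_s, dur)
    # first gap (trace start) gets no post-buffer; last gets no pre-buffer
    starts[1] <- 0
    per <- cbind(starts, ends)
    per <- per[per[, 2] - per[, 1] >= min_duration_s, , drop = FALSE]
  }
  colnames(per) <- c("start_s", "end_s")
  per[per[, 2] - per[, 1] >= min_duration_s, , drop = FALSE]
}

#' Qualifying events for locomotion-triggered averaging
#'
#' Events longer than `min_event_s` (default 5 s) with at least
#' `pre_quiet_s` (default 2 s) of no locomotion before onset. Events whose
#' onset is closer than `pre_quiet_s` to the trace start cannot be
#' verified quiet and are excluded.
#'
#' @inheritParams find_stationary_periods
#' @param min_event_s minimum event duration, s.
#' @param pre_quiet_s required quiet time before onset, s.
#' @return matrix with columns `onset_s`, `offset_s`.
#' @export
extract_lta_events <- function(moving, sample_rate, min_event_s = 5,
                               pre_quiet_s = 2, merge_gap_s = 1) {
  ev <- locomotion_events(moving, sample_rate, merge_gap_s)
  if (nrow(ev) == 0) return(ev)
  keep <- rep(FALSE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    dur <- ev[i, "offset_s"] - ev[i, "onset_s"]
    if (dur <= min_event_s) next
    if (ev[i, "onset_s"] < pre_quiet_s) next
    quiet_from <- ev[i, "onset_s"] - pre_quiet_s
    prior_end <- if (i == 1) -Inf else ev[i - 1, "offset_s"]
    keep[i] <- prior_end <= quiet_from
  }
  ev[keep, , drop = FALSE]
}

#' Basal (stationary-period) value of a signal
#'
#' Mean of the signal over stationary periods; the basal diameter of a
#' vessel is this quantity computed on its diameter trace.
#'
#' @param values numeric signal (e.g. `diameter_trace$values`).
#' @param sample_rate Hz of `values`.
#' @param periods matrix from [find_stationary_periods()].
#' @return mean over stationary samples.
#' @export
basal_value <- function(values, sample_rate, periods) {
  if (inherits(values, "diameter_trace")) {
    sample_rate <- values$frame_rate
    values <- values$values
  }
  if (is.null(periods) || nrow(periods) == 0)
    stop_invalid("no stationary periods; basal value undefined")
  t <- (seq_along(values) - 1) / sample_rate
  sel <- rep(FALSE, length(values))
  for (i in seq_len(nrow(periods)))
    sel <- sel | (t >= periods[i, 1] & t <= periods[i, 2])
  if (!any(sel)) stop_invalid("stationary periods contain no samples")
  mean(values[sel], na.rm = TRUE)
}

#' Locomotion-triggered average of a vessel signal
#'
#' Event-aligned segments of the trace over `window` (default -2 to +10 s
#' around onset), divided by `normalization_reference` (the vessel's
#' basal diameter under vehicle control), then averaged across events with
#' the SEM over events. Events whose window is not fully inside the trace
#' are dropped.
#'
#' @param trace a `diameter_trace`, or numeric vector with `sample_rate`.
#' @param events matrix from [extract_lta_events()].
#' @param normalization_reference basal diameter (um) under vehicle
#'   control used as the normalizer.
#' @param window `c(pre, post)` seconds relative to onset.
#' @param sample_rate Hz (needed when `trace` is a bare vector).
#' @return a `triggered_average`: list with `rel_time`, `mean`, `sem`,
#'   `n_events`, `normalization_reference`, `segments`.
#' @export
locomotion_triggered_average <- function(trace, events,
                                         normalization_reference,
                                         window = c(-2, 10),
                                         sample_rate = NULL) {
  if (inherits(trace, "diameter_trace")) {
    x <- trace$values
    sample_rate <- trace$frame_rate
  } else {
    x <- as.numeric(trace)
    if (is.null(sample_rate)) stop_invalid("sample_rate required")
  }
  if (normalization_reference <= 0)
    stop_invalid("normalization_reference must be positive")
  rel_idx <- seq.int(round(window[1] * sample_rate),
                     round(window[2] * sample_rate))
  rel_time <- rel_idx / sample_rate
  segs <- list()
  for (i in seq_len(nrow(events))) {
    onset_idx <- round(events[i, 1] * sample_rate) + 1L
    idx <- onset_idx + rel_idx
    if (idx[1] < 1 || idx[length(idx)] > length(x)) next
    segs[[length(segs) + 1L]] <- x[idx] / normalization_reference
  }
  if (length(segs) == 0)
    stop_invalid("no qualifying event lies fully inside the trace")
  m <- do.call(rbind, segs)
  structure(
    list(rel_time = rel_time, mean = colMeans(m),
         sem = if (nrow(m) > 1) row_sem(m) else rep(0, ncol(m)),
         n_events = nrow(m),
         normalization_reference = normalization_reference,
         segments = m),
    class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("<triggered_average> %d events, window [%.3g, %.3g] s, peak %.3f\n",
              x$n_events, min(x$rel_time), max(x$rel_time), max(x$mean)))
  invisible(x)
}

#' Locomotion-evoked amplitude of a triggered average
#'
#' Mean of (normalized diameter - 1) over 3-4 s after locomotion onset,
#' expressed as a percentage of the vehicle basal diameter.
#'
#' @param lta a `triggered_average` (normalized so that 1 = vehicle basal).
#' @param interval averaging interval, s after onset (default `c(3, 4)`).
#' @return evoked amplitude, percent.
#' @export
evoked_amplitude <- function(lta, interval = c(3, 4)) {
  sel <- lta$rel_time >= interval[1] & lta$rel_time <= interval[2]
  if (!any(sel)) stop_invalid("interval outside the LTA window")
  mean(lta$mean[sel] - 1) * 100
}

#' Dilation onset time from a triggered average
#'
#' The pre-onset baseline is the mean over -2 to 0 s. A least-squares line
#' is fit through the rising-phase samples whose amplitude lies between
#' 20% and 80% of the peak dilation (samples from onset up to the first
#' crossing of 80%), and the onset is the time where that line crosses the
#' baseline level. If no samples fall in the band (an instantaneous step),
#' the time of the first supra-20% sample is returned and flagged
#' degenerate.
#'
#' @param lta a `triggered_average`.
#' @return list with `onset_s`, `degenerate`.
#' @export
onset_time <- function(lta) {
  base_sel <- lta$rel_time >= -2 & lta$rel_time <= 0
  if (!any(base_sel)) stop_invalid("LTA window lacks a pre-onset baseline")
  baseline <- mean(lta$mean[base_sel])
  post <- lta$rel_time > 0
  amp <- lta$mean - baseline
  peak <- max(amp[post])
  if (peak <= 0) stop_invalid("no peak dilation above baseline")
  ipk <- which(post & amp == peak)[1]
  lo <- 0.2 * peak; hi <- 0.8 * peak
  post_idx <- which(post)
  post_idx <- post_idx[post_idx <= ipk]
  i80 <- post_idx[which(amp[post_idx] >= hi)[1]]
  if (is.na(i80)) i80 <- ipk
  band <- post_idx[post_idx <= i80 & amp[post_idx] >= lo &
                     amp[post_idx] <= hi]
  if (length(band) < 2) {
    first20 <- post_idx[which(amp[post_idx] >= lo)[1]]
    return(list(onset_s = lta$rel_time[first20], degenerate = TRUE))
  }
  fit <- lm(y ~ t, data = data.frame(t = lta$rel_time[band],
                                     y = amp[band]))
  b <- coef(fit)
  list(onset_s = as.numeric(-b[1] / b[2]), degenerate = FALSE)
}

#' Locomotion-induced dilation metric
#'
#' The change from the treatment pre-locomotion baseline, expressed as a
#' percentage of the vehicle-condition basal diameter:
#' `(evoked - baseline) * 100`, with both arguments given as fractions of
#' the vehicle basal diameter. A vessel whose treatment baseline is 0.90
#' of the vehicle basal and whose locomotion-evoked level is 1.05 has a
#' 15% locomotion-induced dilation; a baseline of 1.10 with an evoked
#' level of 1.15 gives 5%. (The two reporting conventions are tied
#' together by `metric + (baseline - 1) * 100 =` the evoked change
#' relative to the vehicle baseline.)
#'
#' @param treatment_baseline pre-locomotion baseline under treatment, as a
#'   fraction of the vehicle basal diameter.
#' @param evoked_level locomotion-evoked level, same normalization.
#' @return locomotion-induced dilation, percent.
#' @export
locomotion_induced_metric <- function(treatment_baseline, evoked_level) {
  (evoked_level - treatment_baseline) * 100
}
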