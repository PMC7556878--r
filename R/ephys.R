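# LFP extraction and state-resolved band power / spectra.

#' Extract the local field potential from a raw neural signal
#'
#' Zero-phase band-pass filtering of the raw signal between 10 and 100 Hz
#' (order-4 Butterworth, forward-backward), followed by a zero-phase 60 Hz
#' notch (second-order IIR, quality factor 45) to remove mains noise.
#'
#' @param raw an `lfp_recording` or numeric vector.
#' @param sample_rate Hz (from the recording when available); must be at
#'   least 200 Hz.
#' @param band band-pass edges, Hz (default `c(10, 100)`).
#' @param notch_hz mains frequency (default 60; `NA` disables the notch).
#' @param notch_q notch quality factor (default 45).
#' @return an `lfp_recording` with filtered samples.
#' @export
extract_lfp <- function(raw, sample_rate = NULL, band = c(10, 100),
                        notch_hz = 60, notch_q = 45) {
  if (inherits(raw, "lfp_recording")) {
    x <- raw$samples
    sample_rate <- sample_rate %||% raw$sample_rate
  } else {
    x <- as.numeric(raw)
    if (is.null(sample_rate)) stop_invalid("sample_rate required")
  }
  if (sample_rate < 200)
    stop_invalid("invalid-rate: sample_rate must be at least 200 Hz")
  y <- fft_butter_filter(x, sample_rate, low = band[1], high = band[2],
                         order = 4)
  if (!is.na(notch_hz)) y <- notch_filter(y, sample_rate, notch_hz, notch_q)
  structure(list(samples = y, sample_rate = sample_rate,
                 band = band, notch_hz = notch_hz),
            class = "lfp_recording")
}

#' State-resolved gamma-band power
#'
#' The signal is zero-phase band-pass filtered to 40-100 Hz (order 4) with
#' a 60 Hz notch, and power is the mean squared amplitude (variance about
#' zero) over the masked samples, computed separately for stationary and
#' locomotion states. Band power as variance of the band-passed signal
#' equals the integrated in-band PSD by Parseval's theorem.
#'
#' @param lfp an `lfp_recording` or numeric vector (+ `sample_rate`).
#' @param state_mask logical vector, TRUE = locomotion, one per sample.
#' @param band gamma band, Hz (default `c(40, 100)`).
#' @param sample_rate Hz when `lfp` is a bare vector.
#' @param notch_hz,notch_q notch parameters (default 60 Hz, Q = 45).
#' @return a `band_power`: list with `band`, `basal_power`,
#'   `locomotion_power`, `ratio` (locomotion / basal).
#' @export
gamma_power <- function(lfp, state_mask, band = c(40, 100),
                        sample_rate = NULL, notch_hz = 60, notch_q = 45) {
  if (inherits(lfp, "lfp_recording")) {
    x <- lfp$samples
    sample_rate <- sample_rate %||% lfp$sample_rate
  } else {
    x <- as.numeric(lfp)
    if (is.null(sample_rate)) stop_invalid("sample_rate required")
  }
  stopifnot(length(state_mask) == length(x))
  y <- fft_butter_filter(x, sample_rate, low = band[1], high = band[2],
                         order = 4)
  if (!is.na(notch_hz)) y <- notch_filter(y, sample_rate, notch_hz, notch_q)
  basal <- mean(y[!state_mask]^2)
  loco <- if (any(state_mask)) mean(y[state_mask]^2) else NA_real_
  structure(list(band = band, basal_power = basal, locomotion_power = loco,
                 ratio = loco / basal),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %g-%g Hz: basal %.4g, locomotion %.4g (ratio %.3f)\n",
              x$band[1], x$band[2], x$basal_power, x$locomotion_power,
              x$ratio))
  invisible(x)
}

#' State-resolved LFP power spectra, normalized to a reference
#'
#' Welch spectra (1 s Hann windows, 50% overlap) are computed separately
#' over stationary and locomotion samples (contiguous state segments of at
#' least one window length), then divided pointwise by
#' `reference_spectrum` -- typically the vehicle-condition stationary
#' spectrum of the same animal. Passing `NULL` uses the recording's own
#' stationary spectrum as reference.
#'
#' @param lfp an `lfp_recording` or numeric vector (+ `sample_rate`).
#' @param state_mask logical, TRUE = locomotion.
#' @param reference_spectrum data.frame (`freq_hz`, `psd`) or `NULL`.
#' @param window_s Welch segment length, s.
#' @param sample_rate Hz when `lfp` is a bare vector.
#' @return data.frame with `freq_hz`, `basal_psd`, `locomotion_psd`,
#'   `basal_ratio`, `locomotion_ratio`.
#' @export
state_spectra <- function(lfp, state_mask, reference_spectrum = NULL,
                          window_s = 1, sample_rate = NULL) {
  if (inherits(lfp, "lfp_recording")) {
    x <- lfp$samples
    sample_rate <- sample_rate %||% lfp$sample_rate
  } else {
    x <- as.numeric(lfp)
    if (is.null(sample_rate)) stop_invalid("sample_rate required")
  }
  state_psd <- function(mask) {
    runs <- logical_runs(mask)
    nfft <- round(sample_rate * window_s)
    runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= nfft, ,
                 drop = FALSE]
    if (nrow(runs) == 0)
      stop_invalid("no state segment is as long as one Welch window")
    acc <- NULL; nseg <- 0
    for (i in seq_len(nrow(runs))) {
      p <- welch_psd(x[runs[i, "start"]:runs[i, "end"]], sample_rate,
                     window_s)
      w <- max(1L, (runs[i, "end"] - runs[i, "start"] + 1L) %/% nfft)
      acc <- if (is.null(acc)) p$psd * w else acc + p$psd * w
      nseg <- nseg + w
      freq <- p$freq_hz
    }
    list(freq = freq, psd = acc / nseg)
  }
  basal <- state_psd(!state_mask)
  loco <- state_psd(state_mask)
  ref <- if (is.null(reference_spectrum)) basal$psd else {
    stopifnot(isTRUE(all.equal(reference_spectrum$freq_hz, basal$freq)))
    reference_spectrum$psd
  }
  data.frame(freq_hz = basal$freq,
             basal_psd = basal$psd, locomotion_psd = loco$psd,
             basal_ratio = basal$psd / ref,
             locomotion_ratio = loco$psd / ref)
}
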