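# Shared numerical helpers: zero-phase filters, spectral estimation,
# run-length utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Zero-phase Butterworth filtering (time domain)
#'
#' Forward-backward (`filtfilt`) application of a Butterworth filter, the
#' zero-lag filtering used throughout the analysis chain. Suitable for
#' corners that are a reasonable fraction of the Nyquist frequency; for
#' very slow corners (e.g. 0.001 Hz at kHz sampling) see
#' [fft_butter_filter()].
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; `NULL` for low-pass/high-pass.
#' @param order filter order (per pass).
#' @return filtered vector, same length as `x`.
#' @keywords internal
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 4) {
  nyq <- fs / 2
  if (!is.null(low) && !is.null(high)) {
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    bf <- signal::butter(order, high / nyq, type = "low")
  } else if (!is.null(low)) {
    bf <- signal::butter(order, low / nyq, type = "high")
  } else {
    return(x)
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase Butterworth filtering (frequency domain)
#'
#' Applies the squared Butterworth magnitude response |H(f)|^2 via the FFT,
#' which is the frequency-domain equivalent of forward-backward IIR
#' filtering. Used for very slow corners (0.001-1 Hz at kHz sampling rates)
#' where a time-domain IIR design is numerically degenerate. The signal is
#' reflection-padded by one period of the slowest corner (capped at the
#' signal length) to suppress edge transients.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz (`NULL` to omit a side).
#' @param order Butterworth order (per pass).
#' @return filtered vector, same length as `x`.
#' @export
fft_butter_filter <- function(x, fs, low = NULL, high = NULL, order = 4) {
  n <- length(x)
  slowest <- min(c(low, high))
  pad <- min(n, ceiling(fs / slowest))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
  np <- length(xp)
  f <- seq(0, np - 1) / np * fs
  f <- ifelse(f > fs / 2, fs - f, f)     # two-sided frequency axis
  if (!is.null(low) && !is.null(high)) {
    # band-pass: |H|^2 of an order-n Butterworth band-pass (unit gain at
    # the geometric center sqrt(low*high))
    bw <- high - low
    xf <- ifelse(f == 0, Inf, (f^2 - low * high) / (f * bw))
    h <- 1 / (1 + xf^(2 * order))
  } else if (!is.null(high)) {
    h <- 1 / (1 + (f / high)^(2 * order))                          # low-pass
  } else {
    r <- ifelse(f == 0, Inf, (low / f)^(2 * order))
    h <- 1 / (1 + r)                                               # high-pass
  }
  y <- Re(fft(fft(xp) * h, inverse = TRUE)) / np
  y[seq.int(pad + 1L, pad + n)]
}

#' Second-order IIR notch filter, applied zero-phase
#'
#' Standard biquad notch centered at `f0` with quality factor `q`
#' (bandwidth `f0/q`), run forward-backward for zero lag.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param f0 notch center frequency, Hz (default 60, mains noise).
#' @param q quality factor (default 45, i.e. ~1.3 Hz bandwidth: narrow
#'   enough to leave neighboring gamma frequencies within 1%, wide enough
#'   to reject a mains tone by more than 20 dB).
#' @return filtered vector.
#' @export
notch_filter <- function(x, fs, f0 = 60, q = 45) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  as.numeric(signal::filtfilt(flt, x))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-tapered segments of `nfft` samples
#' with 50% overlap. Density is one-sided, in units^2/Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window_s segment length in seconds (default 1).
#' @return data.frame with columns `freq_hz`, `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 1) {
  nfft <- max(8L, round(fs * window_s))
  n <- length(x)
  if (n < nfft) stop_invalid("signal shorter than one Welch segment")
  step <- nfft %/% 2L
  starts <- seq.int(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))  # Hann
  u <- sum(w^2)
  nh <- nfft %/% 2L
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[seq.int(s, s + nfft - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (u * fs)
    half <- p[seq_len(nh + 1L)]
    half[2:nh] <- 2 * half[2:nh]       # fold negative frequencies
    acc <- acc + half
  }
  data.frame(freq_hz = seq(0, nh) * fs / nfft, psd = acc / length(starts))
}

# Runs of TRUE in a logical vector as (start, end) sample indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# z-score a vector (mean 0, SD 1).
zscore <- function(x) (x - mean(x)) / sd(x)

# standard error of the mean across rows of a matrix
row_sem <- function(m) apply(m, 2, sd) / sqrt(nrow(m))
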