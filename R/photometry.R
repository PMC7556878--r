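# Fiber-photometry correction: photobleaching (double-exponential decay),
# hemoglobin attenuation (GFP-calibrated linear coupling to the
# blood-volume channel), z-scoring, and duration-binned event averages.

#' Fit a double-exponential photobleaching model
#'
#' The raw channel is zero-phase low-pass filtered below 0.1 Hz; samples
#' during locomotion and the following `exclusion_pad_s` seconds are
#' excluded (behavior-evoked blood-volume changes would contaminate the
#' decay estimate); the remainder is fit with
#' `a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + offset` by nonlinear least
#' squares. The fit is multi-started over tau pairs from {30, 300, 3000} s
#' (amplitudes and offset solved linearly for each start) because
#' two-exponential fits are initialization-sensitive. If no two-exponential
#' start converges, a single-exponential fallback is used and flagged.
#'
#' @param channel raw fluorescence vector (a.u.).
#' @param sample_rate Hz.
#' @param moving logical locomotion mask (same length); `NULL` for a
#'   session with no locomotion.
#' @param exclusion_pad_s seconds excluded after each locomotion offset
#'   (default 15).
#' @param fit_rate_hz the low-passed channel is decimated to about this
#'   rate before fitting (the decay lives below 0.1 Hz, so fitting at a
#'   few Hz loses nothing and keeps the optimizer fast).
#' @return a `bleach_model`: list with `a1`, `tau1`, `a2`, `tau2`,
#'   `offset`, `single_exp_fallback`, `rms_resid`.
#' @export
fit_bleach <- function(channel, sample_rate, moving = NULL,
                       exclusion_pad_s = 15, fit_rate_hz = 5) {
  n <- length(channel)
  t <- (seq_len(n) - 1) / sample_rate
  lp <- fft_butter_filter(channel, sample_rate, high = 0.1, order = 4)
  include <- rep(TRUE, n)
  if (!is.null(moving) && any(moving)) {
    pad <- round(exclusion_pad_s * sample_rate)
    runs <- logical_runs(moving)
    for (i in seq_len(nrow(runs)))
      include[runs[i, "start"]:min(n, runs[i, "end"] + pad)] <- FALSE
  }
  if (sum(include) < 60 * sample_rate)
    stop_invalid("fewer than 60 s of locomotion-free data; cannot fit decay")
  dec <- max(1L, floor(sample_rate / fit_rate_hz))
  sel <- which(include)[seq(1, sum(include), by = dec)]
  td <- t[sel]; yd <- lp[sel]
  if (sd(yd) < 1e-9 * max(abs(yd), 1)) {
    # constant channel: no decay to fit
    return(structure(list(a1 = 0, tau1 = 300, a2 = 0, tau2 = 3000,
                          offset = mean(yd), single_exp_fallback = FALSE,
                          rms_resid = 0),
                     class = "bleach_model"))
  }
  # linear solve for (a1, a2, offset) given a tau pair
  lin_fit <- function(tau1, tau2) {
    X <- cbind(exp(-td / tau1), exp(-td / tau2), 1)
    cf <- tryCatch(qr.coef(qr(X), yd), error = function(e) NULL)
    if (is.null(cf) || any(is.na(cf))) return(NULL)
    list(cf = cf, rss = sum((yd - X %*% cf)^2))
  }
  taus <- c(30, 300, 3000)
  grid <- expand.grid(tau1 = taus, tau2 = taus)
  grid <- grid[grid$tau1 < grid$tau2, ]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    st <- lin_fit(grid$tau1[i], grid$tau2[i])
    if (!is.null(st)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          yd ~ a1 * exp(-td / tau1) + a2 * exp(-td / tau2) + offset,
          start = list(a1 = st$cf[1], tau1 = grid$tau1[i],
                       a2 = st$cf[2], tau2 = grid$tau2[i],
                       offset = st$cf[3]),
          lower = c(-Inf, 1, -Inf, 1, -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(fit = fit, rss = rss)
      }
    }
  }
  fallback <- FALSE
  if (is.null(best)) {
    fallback <- TRUE
    fit1 <- tryCatch(minpack.lm::nlsLM(
      yd ~ a1 * exp(-td / tau1) + offset,
      start = list(a1 = yd[1] - yd[length(yd)], tau1 = 300,
                   offset = yd[length(yd)]),
      lower = c(-Inf, 1, -Inf)), error = function(e) NULL)
    if (is.null(fit1)) {
      params <- c(a1 = 0, tau1 = 300, a2 = 0, tau2 = 3000,
                  offset = mean(yd))
      rms <- sd(yd)
    } else {
      p <- coef(fit1)
      params <- c(a1 = unname(p["a1"]), tau1 = unname(p["tau1"]),
                  a2 = 0, tau2 = unname(p["tau1"]),
                  offset = unname(p["offset"]))
      rms <- sqrt(mean(stats::resid(fit1)^2))
    }
  } else {
    p <- coef(best$fit)
    # report the faster component first
    if (p["tau1"] > p["tau2"])
      p <- c(a1 = unname(p["a2"]), tau1 = unname(p["tau2"]),
             a2 = unname(p["a1"]), tau2 = unname(p["tau1"]),
             offset = unname(p["offset"]))
    params <- p
    rms <- sqrt(best$rss / length(yd))
  }
  structure(as.list(c(params,
                      single_exp_fallback = fallback, rms_resid = rms)),
            class = "bleach_model")
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf(
    "<bleach_model> a1=%.3g tau1=%.3gs a2=%.3g tau2=%.3gs offset=%.3g%s\n",
    x$a1, x$tau1, x$a2, x$tau2, x$offset,
    if (isTRUE(as.logical(x$single_exp_fallback))) " (single-exp fallback)"
    else ""))
  invisible(x)
}

#' Subtract the bleaching fit and normalize a channel
#'
#' The fitted decay (including its offset -- scale is irrelevant because
#' min-max normalization follows) is subtracted from the raw channel; the
#' residual is zero-phase low-pass filtered below 1 Hz; the result is
#' returned both on the debleached scale (`debleached`, used for
#' attenuation-slope estimation, where relative scale between channels
#' matters) and min-max scaled to the unit interval (`normalized`).
#'
#' @param channel raw fluorescence vector.
#' @param model a `bleach_model` from [fit_bleach()].
#' @param sample_rate Hz.
#' @param lowpass_hz residual low-pass corner (default 1 Hz).
#' @return list with `debleached` and `normalized`.
#' @export
debleach_and_normalize <- function(channel, model, sample_rate,
                                   lowpass_hz = 1) {
  t <- (seq_along(channel) - 1) / sample_rate
  fitcurve <- bleach_curve(t, list(a1 = model$a1, tau1 = model$tau1,
                                   a2 = model$a2, tau2 = model$tau2,
                                   offset = model$offset))
  resid <- channel - fitcurve
  lp <- fft_butter_filter(resid, sample_rate, high = lowpass_hz, order = 4)
  rng <- range(lp)
  norm <- if (diff(rng) > 0) (lp - rng[1]) / diff(rng) else lp * 0
  list(debleached = lp, normalized = norm)
}

#' Estimate the hemoglobin attenuation coefficient from GFP controls
#'
#' In animals expressing activity-independent GFP, any shared dynamics
#' between the green channel and the blood-volume (red/TRITC) channel
#' reflect hemoglobin absorption. Per session, both channels are
#' debleached ([fit_bleach()] + [debleach_and_normalize()]) and the
#' ordinary least-squares slope of debleached green on debleached red is
#' computed; the attenuation coefficient is the mean of the slope
#' magnitudes across animals, with the common sign retained so the
#' correction removes (rather than doubles) the coupling.
#'
#' @param gfp_sessions list of `photometry_session` objects (GFP
#'   controls).
#' @return an `attenuation_model`: list with `coeff` (mean |slope|),
#'   `sign` (-1 when blood volume attenuates green, the physiological
#'   case), `per_animal_slopes` (signed).
#' @export
estimate_attenuation <- function(gfp_sessions) {
  if (inherits(gfp_sessions, "photometry_session"))
    gfp_sessions <- list(gfp_sessions)
  slopes <- vapply(gfp_sessions, function(s) {
    bg <- fit_bleach(s$green, s$sample_rate, s$moving)
    br <- fit_bleach(s$red, s$sample_rate, s$moving)
    g <- debleach_and_normalize(s$green, bg, s$sample_rate)$debleached
    r <- debleach_and_normalize(s$red, br, s$sample_rate)$debleached
    unname(coef(lm(g ~ r))[2])
  }, numeric(1))
  structure(list(coeff = mean(abs(slopes)),
                 sign = if (mean(slopes) < 0) -1 else 1,
                 per_animal_slopes = slopes),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf("<attenuation_model> coeff %.4f (sign %+d) from %d animals\n",
              x$coeff, x$sign, length(x$per_animal_slopes)))
  invisible(x)
}

#' Correct the green channel for hemoglobin absorption and z-score
#'
#' The blood-volume channel scaled by the attenuation coefficient is
#' removed from the green channel (`green - sign * coeff * red`, i.e. the
#' attenuated fraction is added back when the coupling is negative), the
#' result is zero-phase band-pass filtered between 0.001 and 1 Hz, and
#' converted to z-scores. The blood-volume channel is band-passed and
#' z-scored the same way.
#'
#' @param green_debleached,red_debleached debleached channels from
#'   [debleach_and_normalize()].
#' @param model an `attenuation_model`.
#' @param sample_rate Hz.
#' @param band band-pass edges, Hz (default `c(0.001, 1)`).
#' @return a `corrected_photometry`: list with `gcamp_z`, `cbv_z`,
#'   `sample_rate`.
#' @export
correct_hemoglobin <- function(green_debleached, red_debleached, model,
                               sample_rate, band = c(0.001, 1)) {
  corrected <- green_debleached -
    model$sign * model$coeff * red_debleached
  cz <- zscore(fft_butter_filter(corrected, sample_rate,
                                 low = band[1], high = band[2], order = 4))
  rz <- zscore(fft_butter_filter(red_debleached, sample_rate,
                                 low = band[1], high = band[2], order = 4))
  structure(list(gcamp_z = cz, cbv_z = rz, sample_rate = sample_rate),
            class = "corrected_photometry")
}

#' Full photometry correction of a session
#'
#' Convenience wrapper: fits the bleach model per channel, debleaches,
#' applies the hemoglobin correction with the supplied attenuation model,
#' and z-scores. Returns the `corrected_photometry` with the bleach models
#' attached.
#'
#' @param session a `photometry_session`.
#' @param attenuation an `attenuation_model` (from GFP controls).
#' @return a `corrected_photometry` with `bleach_green`, `bleach_red`.
#' @export
correct_session <- function(session, attenuation) {
  bg <- fit_bleach(session$green, session$sample_rate, session$moving)
  br <- fit_bleach(session$red, session$sample_rate, session$moving)
  g <- debleach_and_normalize(session$green, bg, session$sample_rate)
  r <- debleach_and_normalize(session$red, br, session$sample_rate)
  out <- correct_hemoglobin(g$debleached, r$debleached, attenuation,
                            session$sample_rate)
  out$bleach_green <- bg
  out$bleach_red <- br
  out
}

#' Duration-binned locomotion-evoked photometry averages
#'
#' Locomotion events at least 5 s long with at least `pre_quiet_s`
#' (default 5 s) of no locomotion before onset are grouped into five
#' duration bins (5-9.99, 10-14.99, 15-29.99, 30-44.99, and
#' 45+ seconds). Per event, the mean over the pre-event window is
#' subtracted; bin-wise averages of both z-scored signals are returned.
#' Each bin is averaged over the window -pre_quiet_s to bin lower edge
#' + 5 s, which every event in the bin covers.
#'
#' @param corrected a `corrected_photometry`.
#' @param moving logical locomotion mask at the photometry rate.
#' @param bins lower edges of the duration bins, s.
#' @param pre_quiet_s required pre-event quiet and baseline window, s.
#' @param merge_gap_s event merge gap, s.
#' @return list of per-bin results (`rel_time`, `gcamp_mean`, `cbv_mean`,
#'   `n_events`), named by bin label; empty bins are `NULL`.
#' @export
event_triggered_photometry <- function(corrected, moving,
                                       bins = c(5, 10, 15, 30, 45),
                                       pre_quiet_s = 5, merge_gap_s = 1) {
  fs <- corrected$sample_rate
  ev <- extract_lta_events(moving, fs, min_event_s = bins[1] - 1e-9,
                           pre_quiet_s = pre_quiet_s,
                           merge_gap_s = merge_gap_s)
  labels <- paste0("[", bins, ",", c(bins[-1] - 0.01, Inf), "]")
  out <- setNames(vector("list", length(bins)), labels)
  if (nrow(ev) == 0) return(out)
  dur <- ev[, "offset_s"] - ev[, "onset_s"]
  bin_of <- findInterval(dur, bins)
  for (b in seq_along(bins)) {
    sel <- which(bin_of == b)
    if (length(sel) == 0) next
    win <- c(-pre_quiet_s, bins[b] + 5)
    rel_idx <- seq.int(round(win[1] * fs), round(win[2] * fs))
    segs_g <- list(); segs_r <- list()
    for (i in sel) {
      onset_idx <- round(ev[i, "onset_s"] * fs) + 1L
      idx <- onset_idx + rel_idx
      if (idx[1] < 1 || idx[length(idx)] > length(corrected$gcamp_z)) next
      pre <- idx[rel_idx < 0]
      g <- corrected$gcamp_z[idx] - mean(corrected$gcamp_z[pre])
      r <- corrected$cbv_z[idx] - mean(corrected$cbv_z[pre])
      segs_g[[length(segs_g) + 1L]] <- g
      segs_r[[length(segs_r) + 1L]] <- r
    }
    if (length(segs_g) == 0) next
    out[[b]] <- list(rel_time = rel_idx / fs,
                     gcamp_mean = colMeans(do.call(rbind, segs_g)),
                     cbv_mean = colMeans(do.call(rbind, segs_r)),
                     n_events = length(segs_g))
  }
  out
}

#' Correlation between corrected activity and blood volume
#'
#' Pearson correlation between the z-scored, hemoglobin-corrected activity
#' signal and the z-scored blood-volume signal over the whole session.
#'
#' @param corrected a `corrected_photometry`.
#' @return Pearson r.
#' @export
signal_blood_correlation <- function(corrected) {
  stats::cor(corrected$gcamp_z, corrected$cbv_z)
}
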