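# Red-blood-cell velocimetry from linescan space-time images via the
# Radon transform.

#' RBC velocity from a linescan image by Radon-transform angle search
#'
#' The image is processed in windows of `window_lines` lines with the given
#' overlap. Per window: the mean is subtracted, the Radon transform is
#' computed over 1-179 degrees (1-degree coarse grid, then a 0.25-degree
#' refinement around the coarse peak with parabolic interpolation of the
#' variance maximum), and the streak angle is the one maximizing the
#' variance of the projection. With the declared convention (rows = time,
#' columns = space), a streak advancing `v_px` pixels per line maximizes
#' projection variance at the angle theta with `tan(theta) = -v_px`, so the
#' velocity is `v = -tan(theta) * pixel_size * line_rate` (positive =
#' increasing column index over time).
#'
#' Windows whose best angle lies within `unresolvable_deg` of 90 degrees
#' (streaks along the space axis, |v| -> infinity) are flagged as
#' unresolvable and returned with `NA` velocity.
#'
#' @param ls a `linescan_image` (see [make_linescan()]), or a plain matrix
#'   with `pixel_size` and `line_rate` supplied.
#' @param window_lines lines per analysis window (default 128).
#' @param overlap fractional window overlap (default 0.5).
#' @param pixel_size,line_rate calibration overrides when `ls` is a matrix.
#' @param unresolvable_deg exclusion half-angle around 90 degrees.
#' @return data.frame of class `velocity_estimates` with columns
#'   `window_start_s`, `velocity_mm_s`, `angle_deg` (streak angle from the
#'   time axis), `separability` (1 - mean/peak projection variance, in
#'   the unit interval), `resolvable`.
#' @export
radon_velocity <- function(ls, window_lines = 128, overlap = 0.5,
                           pixel_size = NULL, line_rate = NULL,
                           unresolvable_deg = 1) {
  if (inherits(ls, "linescan_image")) {
    img <- ls$image
    pixel_size <- pixel_size %||% ls$pixel_size
    line_rate <- line_rate %||% ls$line_rate
  } else {
    img <- ls
    if (is.null(pixel_size) || is.null(line_rate))
      stop_invalid("pixel_size and line_rate required for a bare matrix")
  }
  n_lines <- nrow(img)
  if (window_lines > n_lines)
    stop_invalid("window_lines exceeds the number of lines")
  step <- max(1L, round(window_lines * (1 - overlap)))
  starts <- seq.int(1L, n_lines - window_lines + 1L, by = step)
  coarse <- seq(1, 179, by = 1)
  res <- lapply(starts, function(s) {
    win <- img[seq.int(s, s + window_lines - 1L), , drop = FALSE]
    win <- win - mean(win)
    v_coarse <- proj_variance(win, coarse)
    th0 <- coarse[which.max(v_coarse)]
    fine <- seq(max(th0 - 1, 0.25), min(th0 + 1, 179.75), by = 0.25)
    v_fine <- proj_variance(win, fine)
    k <- which.max(v_fine)
    theta <- fine[k]
    # parabolic sub-step refinement of the variance peak
    if (k > 1 && k < length(v_fine)) {
      denom <- v_fine[k - 1] - 2 * v_fine[k] + v_fine[k + 1]
      if (denom < 0)
        theta <- theta + 0.25 * 0.5 * (v_fine[k - 1] - v_fine[k + 1]) / denom
    }
    sep <- max(0, min(1, 1 - mean(v_coarse) / v_fine[k]))
    resolvable <- abs(theta - 90) > unresolvable_deg
    v_px <- -tan(theta * pi / 180)
    v_mm_s <- v_px * pixel_size * line_rate / 1000
    data.frame(window_start_s = (s - 1) / line_rate,
               velocity_mm_s = if (resolvable) v_mm_s else NA_real_,
               angle_deg = 90 - theta,
               separability = sep,
               resolvable = resolvable)
  })
  out <- do.call(rbind, res)
  attr(out, "convention") <-
    "positive velocity = increasing column index over time"
  class(out) <- c("velocity_estimates", "data.frame")
  out
}

# variance of the Radon projection at each angle
proj_variance <- function(win, angles) {
  rt <- radon_transform(win, angles)
  apply(rt$sinogram, 2, var)
}

#' Filter velocity estimates by projection separability
#'
#' Drops windows whose separability (peak-to-mean projection-variance
#' contrast) falls below a floor, as well as unresolvable windows; the
#' number rejected is reported via a message.
#'
#' @param estimates a `velocity_estimates` data.frame.
#' @param min_separability floor between 0 and 1.
#' @return the retained rows, with `attr(, "n_rejected")` set.
#' @export
velocity_quality_filter <- function(estimates, min_separability = 0.5) {
  keep <- estimates$resolvable & estimates$separability >= min_separability
  out <- estimates[keep, , drop = FALSE]
  n_rej <- sum(!keep)
  message(sprintf("velocity_quality_filter: rejected %d of %d windows",
                  n_rej, length(keep)))
  attr(out, "n_rejected") <- n_rej
  class(out) <- c("velocity_estimates", "data.frame")
  out
}
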