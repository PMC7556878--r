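# Synthetic-data generators. Every generator is a pure function of its
# arguments (including the seed) and attaches its ground truth, so each
# analysis stage can be validated against known inputs.

new_vessel_movie <- function(frames, pixel_size, frame_rate, vessel_class,
                             roi = NULL, axis_line = NULL, ground_truth = NULL) {
  structure(
    list(frames = frames, pixel_size = pixel_size, frame_rate = frame_rate,
         vessel_class = vessel_class,
         roi = roi %||% c(row1 = 1L, row2 = dim(frames)[2],
                          col1 = 1L, col2 = dim(frames)[3]),
         axis_line = axis_line, ground_truth = ground_truth),
    class = "vessel_movie")
}

#' @export
print.vessel_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vessel_movie> %s, %d frames of %dx%d px, %.3g um/px @ %.3g Hz\n",
              x$vessel_class, d[1], d[2], d[3], x$pixel_size, x$frame_rate))
  invisible(x)
}

# Box lumen profile convolved with a Gaussian PSF, evaluated exactly via the
# normal CDF: conv(x) = Phi((x - c + w/2)/sigma) - Phi((x - c - w/2)/sigma).
box_psf_profile <- function(x, center, width, sigma) {
  stats::pnorm((x - center + width / 2) / sigma) -
    stats::pnorm((x - center - width / 2) / sigma)
}

# Poisson photon noise plus Gaussian read noise at a requested SNR.
# SNR is defined as (peak - background) / SD of the background noise,
# with background-noise variance = background counts + read-noise variance.
apply_shot_noise <- function(clean01, snr, background_counts, read_noise_sd) {
  if (!is.finite(snr)) {
    return(background_counts + 100 * clean01)
  }
  amp <- snr * sqrt(background_counts + read_noise_sd^2)
  lambda <- background_counts + amp * clean01
  rpois(length(lambda), lambda) + rnorm(length(lambda), 0, read_noise_sd)
}

#' Synthesize a pial-vessel movie with known diameter
#'
#' Renders a straight, vertically oriented fluorescent vessel whose
#' cross-axis intensity profile is a box of the requested width convolved
#' with a Gaussian point-spread function, over a dark background with
#' Poisson photon noise and Gaussian read noise. Emulates a two-photon
#' movie of a dye-filled pial arteriole at a nominal 8 Hz frame rate.
#'
#' @param diameter_trace vessel lumen diameter per frame, um (all > 0).
#' @param pixel_size um per pixel.
#' @param frame_rate frames per second.
#' @param snr (peak - background) / background-noise SD; `Inf` for a
#'   noiseless movie.
#' @param seed RNG seed; the same seed gives a bit-identical movie.
#' @param n_rows image height (pixels along the vessel axis).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 1).
#' @param background_counts mean background photon count.
#' @param read_noise_sd SD of additive read noise (counts).
#' @return a `vessel_movie` with the true diameter trace attached as
#'   ground truth and `axis_line` running down the vessel center.
#' @export
make_pial_movie <- function(diameter_trace, pixel_size = 0.5, frame_rate = 8,
                            snr = 10, seed = 1, n_rows = 32,
                            psf_sigma_px = 1, background_counts = 20,
                            read_noise_sd = 1) {
  if (any(!is.finite(diameter_trace)) || any(diameter_trace <= 0))
    stop_invalid("diameter_trace must be finite and positive")
  if (pixel_size <= 0 || frame_rate <= 0)
    stop_invalid("pixel_size and frame_rate must be positive")
  if (!is.finite(snr) && snr != Inf || (is.finite(snr) && snr <= 0))
    stop_invalid("snr must be positive (or Inf)")
  n_frames <- length(diameter_trace)
  w_px <- diameter_trace / pixel_size
  n_cols <- 2L * ceiling(max(w_px)) + 21L
  cc <- (n_cols + 1) / 2
  withr::with_seed(seed, {
    frames <- array(0, c(n_frames, n_rows, n_cols))
    xg <- seq_len(n_cols)
    for (i in seq_len(n_frames)) {
      prof <- box_psf_profile(xg, cc, w_px[i], psf_sigma_px)
      clean <- matrix(prof, n_rows, n_cols, byrow = TRUE)
      frames[i, , ] <- apply_shot_noise(clean, snr, background_counts,
                                        read_noise_sd)
    }
  })
  new_vessel_movie(
    frames, pixel_size, frame_rate, "pial",
    axis_line = list(p1 = c(row = 1, col = cc), p2 = c(row = n_rows, col = cc)),
    ground_truth = list(diameter_trace = diameter_trace))
}

#' Parametric lumen boundary for penetrating-vessel phantoms
#'
#' Describes an elliptical cross-section, optionally Fourier-perturbed:
#' in the ellipse frame the boundary radius at polar angle psi is
#' `r_e(psi) * (1 + sum(eps_k * cos(k * psi + phase_k)))`.
#'
#' @param a_px,b_px ellipse semi-axes in pixels.
#' @param phi_rad rotation of the major axis, radians.
#' @param fourier optional list of components, each `list(k=, eps=, phase=)`.
#' @return a `lumen_shape` object with an `area_px2()`-compatible analytic
#'   area computed by [lumen_area_px2()].
#' @export
lumen_shape <- function(a_px, b_px, phi_rad = 0, fourier = NULL) {
  stopifnot(a_px > 0, b_px > 0)
  structure(list(a = a_px, b = b_px, phi = phi_rad, fourier = fourier),
            class = "lumen_shape")
}

# boundary radius at psi (angle in the *rotated* ellipse frame)
lumen_radius <- function(shape, psi) {
  re <- shape$a * shape$b /
    sqrt((shape$b * cos(psi))^2 + (shape$a * sin(psi))^2)
  if (!is.null(shape$fourier)) {
    pert <- rep(0, length(psi))
    for (f in shape$fourier) pert <- pert + f$eps * cos(f$k * psi + f$phase)
    re <- re * (1 + pert)
  }
  re
}

#' Analytic area of a parametric lumen boundary
#'
#' Area = 1/2 * integral of r(psi)^2 d psi, evaluated on a dense angular
#' grid (exact for ellipses to numerical quadrature precision).
#'
#' @param shape a [lumen_shape()].
#' @param n quadrature points.
#' @return area in square pixels.
#' @export
lumen_area_px2 <- function(shape, n = 4096) {
  psi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- lumen_radius(shape, psi)
  sum(r^2) * (2 * pi / n) / 2
}

#' Synthesize a penetrating-arteriole movie with known cross-section
#'
#' Renders a (possibly non-circular, rotating) lumen cross-section per
#' frame: pixels are filled by 4x4 sub-pixel coverage sampling of the
#' parametric boundary, blurred by a Gaussian PSF, and corrupted by
#' Poisson-Gaussian noise. The analytic per-frame area is attached as
#' ground truth.
#'
#' @param shapes a single [lumen_shape()] or a list of one per frame.
#' @param pixel_size um per pixel.
#' @param frame_rate frames per second.
#' @param snr,seed,psf_sigma_px,background_counts,read_noise_sd as in
#'   [make_pial_movie()].
#' @param dim_px image size `c(rows, cols)`.
#' @return a `vessel_movie` of class label `"penetrating"`.
#' @export
make_penetrating_movie <- function(shapes, pixel_size = 0.5, frame_rate = 8,
                                   snr = 10, seed = 1, dim_px = c(64, 64),
                                   psf_sigma_px = 1, background_counts = 20,
                                   read_noise_sd = 1) {
  if (pixel_size <= 0 || frame_rate <= 0)
    stop_invalid("pixel_size and frame_rate must be positive")
  if (inherits(shapes, "lumen_shape")) shapes <- list(shapes)
  n_frames <- length(shapes)
  nr <- dim_px[1]; nc <- dim_px[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  sub <- (seq_len(4) - 2.5) / 4
  offs <- expand.grid(dy = sub, dx = sub)
  area_px2 <- vapply(shapes, lumen_area_px2, numeric(1))
  withr::with_seed(seed, {
    frames <- array(0, c(n_frames, nr, nc))
    yg <- rep(seq_len(nr), times = nc) - cy
    xg <- rep(seq_len(nc), each = nr) - cx
    for (i in seq_len(n_frames)) {
      sh <- shapes[[i]]
      cov <- numeric(nr * nc)
      for (k in seq_len(nrow(offs))) {
        y <- yg + offs$dy[k]; x <- xg + offs$dx[k]
        # rotate into the ellipse frame
        xr <- x * cos(sh$phi) + y * sin(sh$phi)
        yr <- -x * sin(sh$phi) + y * cos(sh$phi)
        rho <- sqrt(xr^2 + yr^2)
        psi <- atan2(yr, xr)
        cov <- cov + (rho <= lumen_radius(sh, psi))
      }
      clean <- matrix(cov / nrow(offs), nr, nc)
      if (psf_sigma_px > 0)
        clean <- EBImage::gblur(clean, sigma = psf_sigma_px)
      frames[i, , ] <- apply_shot_noise(pmax(clean, 0), snr,
                                        background_counts, read_noise_sd)
    }
  })
  new_vessel_movie(
    frames, pixel_size, frame_rate, "penetrating",
    ground_truth = list(area_px2 = area_px2,
                        area_um2 = area_px2 * pixel_size^2,
                        diameter_um = 2 * sqrt(area_px2 * pixel_size^2 / pi)))
}

#' Synthesize a linescan space-time image with known RBC velocity
#'
#' Rows are successive scan lines (time); columns are position along the
#' capillary (space). Red blood cells appear as dark Gaussian streaks on a
#' bright plasma background; a cell moving at v advances
#' `v / (pixel_size * line_rate)` pixels per line (positive velocity =
#' increasing column index over time). Particle positions wrap around the
#' scan length.
#'
#' @param velocity_trace RBC velocity in mm/s: a scalar (constant velocity)
#'   or one value per line.
#' @param pixel_size um per pixel along the scan.
#' @param line_rate lines per second.
#' @param particle_density expected number of cells per pixel of scan
#'   length (0.1 means ~10 cells on a 100-px scan).
#' @param seed RNG seed.
#' @param n_lines number of lines when `velocity_trace` is scalar.
#' @param n_pixels scan length in pixels.
#' @param noise_sd SD of additive Gaussian noise (streak depth is 1).
#' @param particle_sigma_px streak half-width (Gaussian sigma), pixels.
#' @return a `linescan_image` with the per-line velocity attached.
#' @export
make_linescan <- function(velocity_trace, pixel_size = 0.5, line_rate = 2000,
                          particle_density = 0.1, seed = 1, n_lines = 512,
                          n_pixels = 100, noise_sd = 0,
                          particle_sigma_px = 1) {
  if (pixel_size <= 0 || line_rate <= 0)
    stop_invalid("pixel_size and line_rate must be positive")
  if (length(velocity_trace) > 1) n_lines <- length(velocity_trace)
  v <- rep_len(velocity_trace, n_lines)
  v_px <- v * 1000 / (pixel_size * line_rate)   # mm/s -> px per line
  pos_shift <- cumsum(v_px) - v_px[1]
  n_part <- max(1L, round(particle_density * n_pixels))
  withr::with_seed(seed, {
    x0 <- runif(n_part, 0, n_pixels)
    img <- matrix(0, n_lines, n_pixels)
    xg <- seq_len(n_pixels)
    for (p in seq_len(n_part)) {
      xp <- (x0[p] + pos_shift) %% n_pixels
      d <- outer(xp, xg, `-`)
      d <- (d + n_pixels / 2) %% n_pixels - n_pixels / 2   # wrapped distance
      img <- img - exp(-d^2 / (2 * particle_sigma_px^2))
    }
    img <- img + 1
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  })
  structure(
    list(image = img, pixel_size = pixel_size, line_rate = line_rate,
         convention = "rows = time (line index), cols = space; positive v = increasing column",
         ground_truth = list(velocity_mm_s = v)),
    class = "linescan_image")
}

#' Synthesize a treadmill-encoder velocity trace with known bouts
#'
#' A rotary encoder reads exactly zero while the wheel is still, so the
#' trace is identically zero outside bouts. Each bout is a raised-cosine
#' ramp up to `peak_speed`, with Gaussian jitter (`noise_sd`) added only
#' while the wheel is moving -- the movement jitter is what keeps the
#' filtered acceleration above the binarization threshold throughout a
#' bout.
#'
#' @param bout_times matrix/list of (onset_s, offset_s) rows; must be
#'   ordered, non-overlapping, offsets > onsets.
#' @param duration_s total trace duration, s.
#' @param sample_rate encoder sampling rate, Hz (default 1000).
#' @param peak_speed bout plateau speed, cm/s.
#' @param noise_sd running-jitter SD, cm/s.
#' @param ramp_s raised-cosine ramp duration at bout edges, s.
#' @param seed RNG seed.
#' @return a `locomotion_trace` with true bout times attached.
#' @export
make_locomotion_trace <- function(bout_times, duration_s, sample_rate = 1000,
                                  peak_speed = 10, noise_sd = 0.5,
                                  ramp_s = 0.3, seed = 1) {
  if (sample_rate <= 0) stop_invalid("sample_rate must be positive")
  bouts <- if (is.list(bout_times)) do.call(rbind, bout_times) else bout_times
  if (is.null(bouts)) bouts <- matrix(numeric(0), 0, 2)
  bouts <- matrix(as.numeric(bouts), ncol = 2)
  if (nrow(bouts) > 0) {
    if (any(bouts[, 2] <= bouts[, 1]))
      stop_invalid("bout offsets must exceed onsets")
    if (nrow(bouts) > 1 &&
        any(bouts[-1, 1] <= bouts[-nrow(bouts), 2]))
      stop_invalid("bouts must be ordered and non-overlapping")
  }
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- numeric(n)
  for (i in seq_len(nrow(bouts))) {
    on <- bouts[i, 1]; off <- bouts[i, 2]
    r <- pmin(ramp_s, (off - on) / 2)
    seg <- t >= on & t <= off
    e <- rep(1, sum(seg))
    ts <- t[seg]
    up <- ts < on + r
    dn <- ts > off - r
    e[up] <- 0.5 - 0.5 * cos(pi * (ts[up] - on) / r)
    e[dn] <- 0.5 - 0.5 * cos(pi * (off - ts[dn]) / r)
    env[seg] <- e
  }
  withr::with_seed(seed, {
    v <- env * peak_speed
    moving <- env > 0
    if (noise_sd > 0 && any(moving))
      v[moving] <- v[moving] + rnorm(sum(moving), 0, noise_sd)
  })
  structure(
    list(velocity = v, sample_rate = sample_rate,
         ground_truth = list(bout_times = bouts)),
    class = "locomotion_trace")
}

# 1/f ("pink") noise with unit variance, generated by FFT spectral shaping.
pink_noise <- function(n, fs, f_min = 0.5) {
  w <- rnorm(n)
  W <- fft(w)
  f <- seq(0, n - 1) / n * fs
  f <- ifelse(f > fs / 2, fs - f, f)
  shape <- 1 / sqrt(pmax(f, f_min))
  shape[1] <- 0
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Synthesize a local field potential with state-dependent gamma power
#'
#' Pink-noise background plus a 40-100 Hz band-limited component whose
#' variance is multiplied by `gamma_gain` while the animal is locomoting,
#' with an optional 60 Hz mains contaminant. Defaults make the 40-100 Hz
#' band gamma-dominated, as in awake cortical recordings.
#'
#' @param bout_mask logical vector, TRUE during locomotion, one entry per
#'   LFP sample.
#' @param sample_rate Hz (default 20000).
#' @param gamma_gain locomotion/stationary gamma variance ratio.
#' @param seed RNG seed.
#' @param pink_sd SD of the pink-noise background, uV.
#' @param gamma_sd stationary-state SD of the gamma component, uV.
#' @param line_amp amplitude of the 60 Hz contaminant, uV (0 = off).
#' @return an `lfp_recording` (samples in uV + metadata).
#' @export
make_lfp <- function(bout_mask, sample_rate = 20000, gamma_gain = 1, seed = 1,
                     pink_sd = 0.5, gamma_sd = 1, line_amp = 0) {
  if (sample_rate <= 0) stop_invalid("sample_rate must be positive")
  n <- length(bout_mask)
  withr::with_seed(seed, {
    bg <- pink_sd * pink_noise(n, sample_rate)
    g <- fft_butter_filter(rnorm(n), sample_rate, low = 40, high = 100,
                           order = 4)
    g <- gamma_sd * g / sd(g)
    g[bout_mask] <- g[bout_mask] * sqrt(gamma_gain)
    x <- bg + g
    if (line_amp > 0) {
      t <- (seq_len(n) - 1) / sample_rate
      x <- x + line_amp * sin(2 * pi * 60 * t)
    }
  })
  structure(
    list(samples = x, sample_rate = sample_rate,
         ground_truth = list(gamma_gain = gamma_gain,
                             bout_mask = bout_mask)),
    class = "lfp_recording")
}

# double-exponential photobleaching curve
bleach_curve <- function(t, p) {
  p[["a1"]] * exp(-t / p[["tau1"]]) + p[["a2"]] * exp(-t / p[["tau2"]]) +
    p[["offset"]]
}

#' Synthesize activity and blood-volume traces driven by locomotion bouts
#'
#' Convenience generator for [make_photometry()] inputs: the calcium trace
#' is the bout indicator convolved with a fast difference-of-exponentials
#' kernel (0.5 s rise, 2 s decay); the blood-volume (CBV) trace uses a
#' slower kernel (1 s rise, 8 s decay), mimicking the venous contribution.
#'
#' @param bout_times matrix of (onset_s, offset_s) rows.
#' @param duration_s trace duration, s.
#' @param sample_rate Hz.
#' @param calcium_amp,cbv_amp response amplitudes (a.u.).
#' @return list with `calcium`, `cbv`, and the `moving` indicator.
#' @export
make_activity_traces <- function(bout_times, duration_s, sample_rate = 1200,
                                 calcium_amp = 1, cbv_amp = 1) {
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  moving <- rep(FALSE, n)
  bouts <- matrix(as.numeric(bout_times), ncol = 2)
  for (i in seq_len(nrow(bouts)))
    moving[t >= bouts[i, 1] & t <= bouts[i, 2]] <- TRUE
  kern <- function(rise, decay) {
    tk <- seq(0, 6 * decay, by = 1 / sample_rate)
    k <- exp(-tk / decay) - exp(-tk / rise)
    k / sum(k)
  }
  conv_ind <- function(k) {
    # causal FFT convolution of the bout indicator with the kernel
    m <- nextn(n + length(k), 2)
    x <- c(as.numeric(moving), rep(0, m - n))
    kk <- c(k, rep(0, m - length(k)))
    Re(fft(fft(x) * fft(kk), inverse = TRUE) / m)[seq_len(n)]
  }
  list(calcium = calcium_amp * conv_ind(kern(0.5, 2)),
       cbv = cbv_amp * conv_ind(kern(1, 8)),
       moving = moving)
}

#' Synthesize a two-channel fiber-photometry session
#'
#' Green channel = photobleaching decay + calcium signal - attenuation_coeff
#' x CBV + noise (hemoglobin absorbs the green fluorescence, so blood-volume
#' increases attenuate it); red channel = its own (half-amplitude) bleaching
#' decay + CBV + noise. Emulates simultaneous GCaMP/GFP and TRITC
#' measurements at 1.2 kHz.
#'
#' @param calcium_trace activity signal, a.u. (constant for a GFP control).
#' @param cbv_trace blood-volume signal, a.u., same length.
#' @param bleach_params named vector `c(a1, tau1, a2, tau2, offset)` (a.u.,
#'   s) for the green channel; the red channel uses the same time constants
#'   with amplitudes halved.
#' @param attenuation_coeff hemoglobin attenuation slope (unitless).
#' @param sample_rate Hz (default 1200).
#' @param noise_sd additive Gaussian noise SD per channel, a.u.
#' @param seed RNG seed.
#' @param moving optional logical locomotion mask, one per sample.
#' @return a `photometry_session`.
#' @export
make_photometry <- function(calcium_trace, cbv_trace,
                            bleach_params = c(a1 = 1, tau1 = 100, a2 = 0.5,
                                              tau2 = 1000, offset = 1),
                            attenuation_coeff = 0.3, sample_rate = 1200,
                            noise_sd = 0, seed = 1, moving = NULL) {
  stopifnot(length(calcium_trace) == length(cbv_trace))
  if (bleach_params[["tau1"]] <= 0 || bleach_params[["tau2"]] <= 0)
    stop_invalid("bleach time constants must be positive")
  n <- length(calcium_trace)
  t <- (seq_len(n) - 1) / sample_rate
  red_params <- bleach_params
  red_params[c("a1", "a2")] <- red_params[c("a1", "a2")] / 2
  withr::with_seed(seed, {
    green <- bleach_curve(t, bleach_params) + calcium_trace -
      attenuation_coeff * cbv_trace
    red <- bleach_curve(t, red_params) + cbv_trace
    if (noise_sd > 0) {
      green <- green + rnorm(n, 0, noise_sd)
      red <- red + rnorm(n, 0, noise_sd)
    }
  })
  structure(
    list(green = green, red = red, sample_rate = sample_rate,
         moving = moving,
         ground_truth = list(calcium = calcium_trace, cbv = cbv_trace,
                             bleach_params = bleach_params,
                             attenuation_coeff = attenuation_coeff)),
    class = "photometry_session")
}

#' Synthesize a multi-animal vessel cohort under the mixed-effects model
#'
#' Generates per-vessel vehicle and treatment diameters such that the
#' fractional diameter change obeys
#' `dD[n, a] = gamma + beta[a] + eps[n, a]`, with animal random intercepts
#' `beta[a] ~ N(0, sigma_animal^2)` and residuals
#' `eps ~ N(0, sigma_resid^2)`.
#'
#' @param gamma fixed treatment effect (fractional change, e.g. -0.25).
#' @param sigma_animal SD of the animal random intercept.
#' @param sigma_resid residual SD.
#' @param n_animals,vessels_per_animal design size.
#' @param baseline_mean_um,baseline_sd_um vehicle-diameter distribution
#'   (truncated below at 8 um).
#' @param vessel_class label column value.
#' @param seed RNG seed.
#' @return a `data.frame` (animal_id, vessel_id, vessel_class,
#'   d_vehicle_um, d_treatment_um) with the true effects in
#'   `attr(, "ground_truth")`.
#' @export
make_cohort <- function(gamma, sigma_animal, sigma_resid, n_animals = 6,
                        vessels_per_animal = 5, baseline_mean_um = 20,
                        baseline_sd_um = 5, vessel_class = "pial", seed = 1) {
  withr::with_seed(seed, {
    beta <- rnorm(n_animals, 0, sigma_animal)
    rows <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
      d0 <- pmax(rnorm(vessels_per_animal, baseline_mean_um, baseline_sd_um),
                 8)
      eps <- rnorm(vessels_per_animal, 0, sigma_resid)
      dd <- gamma + beta[a] + eps
      data.frame(animal_id = sprintf("A%02d", a),
                 vessel_id = sprintf("A%02d_V%02d", a,
                                     seq_len(vessels_per_animal)),
                 vessel_class = vessel_class,
                 d_vehicle_um = d0,
                 d_treatment_um = d0 * (1 + dd))
    }))
  })
  attr(rows, "ground_truth") <- list(gamma = gamma, beta_a = beta,
                                     sigma_animal = sigma_animal,
                                     sigma_resid = sigma_resid)
  rows
}
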