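# End-to-end synthetic demonstration pipeline: generate every modality,
# run each analysis stage, and write one JSON report plus CSV/TIFF
# artifacts. Serves as the executable, seed-deterministic audit of the
# whole chain.

#' Default pipeline configuration
#'
#' All stage parameters in one list: synthetic-recording sizes and rates,
#' analysis defaults, the RNG seed and the output directory. The defaults
#' mirror the recording conventions of the analysis (8 Hz vessel movies,
#' 2 kHz linescans, 1 kHz encoder, 20 kHz electrophysiology, 1.2 kHz
#' photometry), scaled to desk-size durations.
#'
#' @param seed integer RNG seed.
#' @param out_dir output directory (`NULL` = no files written).
#' @return a `pipeline_config` list; unknown keys passed via `...` are an
#'   error.
#' @param ... overrides for any listed field.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL, ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    movie_frame_rate = 8, movie_pixel_size = 0.5, movie_snr = 10,
    movie_duration_s = 60,
    basal_diameter_um = 20, dilation_frac = 0.15,
    linescan_line_rate = 2000, linescan_pixel_size = 0.5,
    linescan_velocity_mm_s = 2, linescan_lines = 1024,
    encoder_rate = 1000, peak_speed_cm_s = 10, encoder_noise_sd = 0.5,
    accel_threshold = 0.3,
    lfp_rate = 20000, gamma_gain = 2,
    phot_rate = 1200, phot_duration_s = 900, phot_noise_sd = 0.02,
    attenuation_coeff = 0.3,
    bleach_params = c(a1 = 1, tau1 = 100, a2 = 0.5, tau2 = 1000,
                      offset = 1),
    cohort_gamma = -0.25, cohort_sigma_animal = 0.05,
    cohort_sigma_resid = 0.05, cohort_n_animals = 6,
    cohort_vessels_per_animal = 5)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates a locomotion session and, from it, a pial-vessel movie, a
#' linescan, an LFP recording, photometry sessions and a vessel cohort;
#' then runs diameter extraction (FWHM + conditioning), velocimetry,
#' behavior segmentation, locomotion-triggered averaging with evoked
#' amplitude and onset time, gamma-band power, photometry correction and
#' the mixed-effects comparison. Returns (and optionally writes) a report
#' with every stage's headline numbers, including the two
#' convention-check values of the locomotion-induced dilation metric.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list; with `config$out_dir` set, artifacts
#'   and `report.json` are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  seeds <- cfg$seed * 1000L + seq_len(20L)

  # --- behavior session shared by movie / LFP stages
  bouts <- rbind(c(10, 18), c(30, 42), c(50, 56.5))
  loco <- make_locomotion_trace(bouts, duration_s = cfg$movie_duration_s,
                                sample_rate = cfg$encoder_rate,
                                peak_speed = cfg$peak_speed_cm_s,
                                noise_sd = cfg$encoder_noise_sd,
                                seed = seeds[1])
  moving <- binarize_locomotion(loco, accel_threshold = cfg$accel_threshold)
  events <- extract_lta_events(moving, cfg$encoder_rate)
  stat_per <- find_stationary_periods(moving, cfg$encoder_rate)

  # --- pial movie: basal diameter with smooth locomotion-locked dilation
  n_frames <- round(cfg$movie_duration_s * cfg$movie_frame_rate)
  tf <- (seq_len(n_frames) - 1) / cfg$movie_frame_rate
  dil <- numeric(n_frames)
  for (i in seq_len(nrow(bouts))) {
    rise <- stats::plogis((tf - bouts[i, 1] - 1.5) / 0.5)
    fall <- stats::plogis((tf - bouts[i, 2] - 2) / 1.2)
    dil <- pmax(dil, rise - fall)
  }
  true_d <- cfg$basal_diameter_um * (1 + cfg$dilation_frac * dil)
  movie <- make_pial_movie(true_d, pixel_size = cfg$movie_pixel_size,
                           frame_rate = cfg$movie_frame_rate,
                           snr = cfg$movie_snr, seed = seeds[2])
  trace <- fwhm_diameter_trace(movie)
  trace <- median_filter_trace(despike_trace(trace))
  fr_moving <- moving[pmin(length(moving),
                           round(tf * cfg$encoder_rate) + 1L)]
  fr_stat <- find_stationary_periods(fr_moving, cfg$movie_frame_rate)
  basal <- basal_value(trace$values, cfg$movie_frame_rate, fr_stat)
  lta <- locomotion_triggered_average(trace, events, basal)
  evoked <- evoked_amplitude(lta)
  onset <- onset_time(lta)

  # --- linescan velocimetry
  ls <- make_linescan(cfg$linescan_velocity_mm_s,
                      pixel_size = cfg$linescan_pixel_size,
                      line_rate = cfg$linescan_line_rate,
                      n_lines = cfg$linescan_lines, noise_sd = 0.2,
                      seed = seeds[3])
  vel <- velocity_quality_filter(radon_velocity(ls), 0.2)

  # --- LFP gamma power (decimated mask; short segment at full rate)
  lfp_dur <- min(cfg$movie_duration_s, 60)
  n_lfp <- round(lfp_dur * cfg$lfp_rate)
  lfp_mask <- moving[pmin(length(moving),
                          round((seq_len(n_lfp) - 1) / cfg$lfp_rate *
                                  cfg$encoder_rate) + 1L)]
  lfp <- make_lfp(lfp_mask, sample_rate = cfg$lfp_rate,
                  gamma_gain = cfg$gamma_gain, seed = seeds[4])
  gp <- gamma_power(lfp, lfp_mask)

  # --- photometry: GFP calibration + GCaMP session
  phot_bouts <- rbind(c(60, 68), c(200, 212), c(400, 407), c(600, 620),
                      c(800, 806))
  phot_bouts <- phot_bouts[phot_bouts[, 2] < cfg$phot_duration_s - 20, ,
                           drop = FALSE]
  act <- make_activity_traces(phot_bouts, cfg$phot_duration_s,
                              cfg$phot_rate)
  gfp <- lapply(seeds[5:7], function(s)
    make_photometry(rep(0, length(act$cbv)), act$cbv,
                    bleach_params = cfg$bleach_params,
                    attenuation_coeff = cfg$attenuation_coeff,
                    sample_rate = cfg$phot_rate,
                    noise_sd = cfg$phot_noise_sd, seed = s,
                    moving = act$moving))
  atten <- estimate_attenuation(gfp)
  sess <- make_photometry(act$calcium, act$cbv,
                          bleach_params = cfg$bleach_params,
                          attenuation_coeff = cfg$attenuation_coeff,
                          sample_rate = cfg$phot_rate,
                          noise_sd = cfg$phot_noise_sd, seed = seeds[8],
                          moving = act$moving)
  corr <- correct_session(sess, atten)
  r_blood <- signal_blood_correlation(corr)

  # --- cohort statistics
  cohort <- make_cohort(cfg$cohort_gamma, cfg$cohort_sigma_animal,
                        cfg$cohort_sigma_resid, cfg$cohort_n_animals,
                        cfg$cohort_vessels_per_animal, seed = seeds[9])
  lme <- fit_lme_delta(cohort, n_groups = 6)

  report <- list(
    config = unclass(cfg),
    diameter = list(
      basal_um = basal,
      true_basal_um = cfg$basal_diameter_um,
      evoked_amplitude_pct = evoked,
      onset_time_s = onset$onset_s,
      n_events = lta$n_events),
    metric_convention_check = list(
      constricted_baseline = locomotion_induced_metric(0.90, 1.05),
      dilated_baseline = locomotion_induced_metric(1.10, 1.15)),
    velocity = list(
      mean_mm_s = mean(vel$velocity_mm_s),
      true_mm_s = cfg$linescan_velocity_mm_s,
      n_windows = nrow(vel)),
    gamma = list(ratio = gp$ratio, true_gain = cfg$gamma_gain),
    photometry = list(
      attenuation_coeff = atten$coeff,
      true_coeff = cfg$attenuation_coeff,
      calcium_correlation = stats::cor(corr$gcamp_z,
                                       sess$ground_truth$calcium),
      blood_correlation = r_blood),
    lme = list(gamma = lme$gamma, se = lme$gamma_se, p_raw = lme$p_raw,
               p_corrected = lme$p_corrected,
               true_gamma = cfg$cohort_gamma))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_movie_tiff(movie, file.path(cfg$out_dir, "pial_movie.tif"))
    write_movie_tiff(ls, file.path(cfg$out_dir, "linescan.tif"))
    write_trace_csv(trace$values, cfg$movie_frame_rate,
                    file.path(cfg$out_dir, "diameter_trace.csv"),
                    "diameter_um",
                    extra = data.frame(despiked = trace$despiked_mask))
    write_trace_csv(loco$velocity, cfg$encoder_rate,
                    file.path(cfg$out_dir, "locomotion.csv"),
                    "velocity_cm_s")
    write.csv(as.data.frame(vel),
              file.path(cfg$out_dir, "velocity.csv"), row.names = FALSE)
    write_cohort_csv(cohort, file.path(cfg$out_dir, "cohort.csv"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  basal diameter      %.2f um (true %.2f)\n",
              x$diameter$basal_um, x$diameter$true_basal_um))
  cat(sprintf("  evoked amplitude    %.1f%% | onset %.2f s\n",
              x$diameter$evoked_amplitude_pct, x$diameter$onset_time_s))
  cat(sprintf("  metric check        %.0f%% / %.0f%%\n",
              x$metric_convention_check$constricted_baseline,
              x$metric_convention_check$dilated_baseline))
  cat(sprintf("  RBC velocity        %.2f mm/s (true %.2f)\n",
              x$velocity$mean_mm_s, x$velocity$true_mm_s))
  cat(sprintf("  gamma power ratio   %.2f (true gain %.2f)\n",
              x$gamma$ratio, x$gamma$true_gain))
  cat(sprintf("  attenuation coeff   %.3f (true %.3f), calcium r %.3f\n",
              x$photometry$attenuation_coeff, x$photometry$true_coeff,
              x$photometry$calcium_correlation))
  cat(sprintf("  LME gamma           %.3f +/- %.3f, p_corr %.3g (true %.2f)\n",
              x$lme$gamma, x$lme$se, x$lme$p_corrected, x$lme$true_gamma))
  invisible(x)
}
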