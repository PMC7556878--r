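# Shared fixtures: all inputs are generated in code with fixed seeds.

# mean TiRS area over the frames of a noisy movie (the unit of measurement
# in practice is a trace, not a single frame)
mean_tirs_area <- function(movie, ...) {
  n <- dim(movie$frames)[1]
  mean(vapply(seq_len(n), function(i)
    tirs_area(movie$frames[i, , ], pixel_size = movie$pixel_size, ...)$area,
    numeric(1)))
}

# moving mask with given bouts at a given rate, no detection involved
bout_mask <- function(bouts, duration_s, fs) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  m <- rep(FALSE, length(t))
  for (i in seq_len(nrow(bouts)))
    m[t >= bouts[i, 1] & t <= bouts[i, 2]] <- TRUE
  m
}

# a small photometry world: bout-driven calcium/CBV plus sessions
make_phot_world <- function(duration_s = 600, fs = 1200,
                            bleach = c(a1 = 1, tau1 = 30, a2 = 0.5,
                                       tau2 = 300, offset = 1),
                            coeff = 0.3, noise_sd = 0.02, seed = 1) {
  bouts <- rbind(c(100, 108), c(300, 312), c(500, 507))
  bouts <- bouts[bouts[, 2] < duration_s - 20, , drop = FALSE]
  act <- make_activity_traces(bouts, duration_s, fs)
  gfp <- lapply(seed + 0:2, function(s)
    make_photometry(rep(0, length(act$cbv)), act$cbv, bleach_params = bleach,
                    attenuation_coeff = coeff, sample_rate = fs,
                    noise_sd = noise_sd, seed = s, moving = act$moving))
  sess <- make_photometry(act$calcium, act$cbv, bleach_params = bleach,
                          attenuation_coeff = coeff, sample_rate = fs,
                          noise_sd = noise_sd, seed = seed + 10,
                          moving = act$moving)
  list(act = act, gfp = gfp, sess = sess, bleach = bleach, coeff = coeff,
       fs = fs)
}
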