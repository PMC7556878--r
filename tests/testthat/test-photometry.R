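# Photobleaching fit, hemoglobin-attenuation correction, z-scoring, and
# event-triggered averages. Sessions here use 600 s at 1.2 kHz with decay
# constants 30/300 s so the whole chain stays fast; the longer-decay
# regime is exercised by the acceptance suite.

world <- make_phot_world(seed = 21)

test_that("the double-exponential decay fit recovers known parameters", {
  bm <- fit_bleach(world$gfp[[1]]$green, world$fs, world$act$moving)
  expect_false(as.logical(bm$single_exp_fallback))
  expect_equal(bm$a1, world$bleach[["a1"]], tolerance = 0.1)
  expect_equal(bm$tau1, world$bleach[["tau1"]], tolerance = 0.1)
  expect_equal(bm$a2, world$bleach[["a2"]], tolerance = 0.1)
  expect_equal(bm$tau2, world$bleach[["tau2"]], tolerance = 0.1)
  # residual RMS small relative to the initial amplitude
  expect_lt(bm$rms_resid / (world$bleach[["a1"]] + world$bleach[["a2"]]),
            0.05)
})

test_that("a constant channel fits with near-zero decay amplitudes", {
  bm <- fit_bleach(rep(2, 1200 * 120), 1200)
  expect_lt(abs(bm$a1) + abs(bm$a2), 0.01)
  expect_error(fit_bleach(rep(2, 1200 * 30), 1200), "60 s")
})

test_that("debleaching normalizes to the unit interval, affine-invariantly", {
  ch <- world$gfp[[1]]$green
  bm <- fit_bleach(ch, world$fs, world$act$moving)
  out <- debleach_and_normalize(ch, bm, world$fs)
  expect_equal(range(out$normalized), c(0, 1))
  # an affine transform of the input yields the identical normalized trace
  ch2 <- 3 * ch + 7
  bm2 <- fit_bleach(ch2, world$fs, world$act$moving)
  out2 <- debleach_and_normalize(ch2, bm2, world$fs)
  expect_equal(out2$normalized, out$normalized, tolerance = 1e-4)
  # a pure monotone decay flattens out after subtraction
  t <- (seq_len(world$fs * 300) - 1) / world$fs
  dec <- 2 * exp(-t / 50) + 1
  bmd <- fit_bleach(dec, world$fs)
  res <- debleach_and_normalize(dec, bmd, world$fs)$debleached
  expect_lt(sd(res), 0.01 * 2)
})

test_that("GFP controls recover the attenuation coefficient within 5%", {
  at <- estimate_attenuation(world$gfp)
  expect_equal(at$coeff, world$coeff, tolerance = 0.05)
  expect_identical(at$sign, -1)
  expect_equal(at$coeff, mean(abs(at$per_animal_slopes)))
  # attenuation-free green is uncoupled from blood volume
  free <- make_photometry(rep(0, length(world$act$cbv)), world$act$cbv,
                          bleach_params = world$bleach,
                          attenuation_coeff = 0, sample_rate = world$fs,
                          noise_sd = 0.02, seed = 3,
                          moving = world$act$moving)
  at0 <- estimate_attenuation(list(free))
  expect_lt(at0$coeff, 0.03)
})

test_that("per-animal slopes average into the cohort coefficient", {
  gfp_mixed <- lapply(seq_along(c(0.2, 0.3, 0.4)), function(i)
    make_photometry(rep(0, length(world$act$cbv)), world$act$cbv,
                    bleach_params = world$bleach,
                    attenuation_coeff = c(0.2, 0.3, 0.4)[i],
                    sample_rate = world$fs, noise_sd = 0.01, seed = i,
                    moving = world$act$moving))
  at <- estimate_attenuation(gfp_mixed)
  expect_equal(at$coeff, 0.3, tolerance = 0.05)
})

test_that("hemoglobin correction restores the programmed calcium signal", {
  at <- estimate_attenuation(world$gfp)
  corr <- correct_session(world$sess, at)
  expect_gt(cor(corr$gcamp_z, world$act$calcium), 0.95)
  # z-score contract
  expect_lt(abs(mean(corr$gcamp_z)), 1e-6)
  expect_equal(sd(corr$gcamp_z), 1, tolerance = 1e-6)
  expect_lt(abs(mean(corr$cbv_z)), 1e-6)
  expect_equal(sd(corr$cbv_z), 1, tolerance = 1e-6)
})

test_that("with a zero coefficient the output is just z-scored green", {
  bg <- fit_bleach(world$sess$green, world$fs, world$act$moving)
  g <- debleach_and_normalize(world$sess$green, bg, world$fs)$debleached
  zero <- structure(list(coeff = 0, sign = -1, per_animal_slopes = 0),
                    class = "attenuation_model")
  corr <- correct_hemoglobin(g, g * 0, zero, world$fs)
  direct <- (function(x) (x - mean(x)) / sd(x))(
    fft_butter_filter(g, world$fs, low = 0.001, high = 1, order = 4))
  expect_equal(corr$gcamp_z, direct, tolerance = 1e-10)
})

test_that("correcting a GFP session decouples green from blood volume", {
  at <- estimate_attenuation(world$gfp)
  corr <- correct_session(world$gfp[[2]], at)
  expect_lt(abs(cor(corr$gcamp_z, corr$cbv_z)), 0.1)
})

test_that("signal-blood correlation matches construction", {
  x <- structure(list(gcamp_z = c(1, -1, 2, -2), cbv_z = c(1, -1, 2, -2),
                      sample_rate = 1),
                 class = "corrected_photometry")
  expect_equal(signal_blood_correlation(x), 1)
  set.seed(8)
  n <- 1e5
  y <- structure(list(gcamp_z = rnorm(n), cbv_z = rnorm(n),
                      sample_rate = 1),
                 class = "corrected_photometry")
  expect_lt(abs(signal_blood_correlation(y)), 0.1)
})

test_that("event-triggered averages are binned by duration and baselined", {
  fs <- 100
  n <- 400 * fs
  t <- (seq_len(n) - 1) / fs
  bouts <- rbind(c(50, 57), c(150, 157.5), c(250, 262), c(330, 346))
  moving <- bout_mask(bouts, 400, fs)
  z <- rep(0, n)
  for (i in seq_len(nrow(bouts)))
    z[t >= bouts[i, 1] & t <= bouts[i, 2] + 2] <- 2
  corr <- structure(list(gcamp_z = z, cbv_z = z / 2, sample_rate = fs),
                    class = "corrected_photometry")
  out <- event_triggered_photometry(corr, moving)
  n_ev <- vapply(out, function(b) if (is.null(b)) 0L else b$n_events,
                 integer(1))
  expect_identical(unname(n_ev), c(2L, 1L, 1L, 0L, 0L))
  b1 <- out[[1]]
  during <- b1$rel_time > 1 & b1$rel_time < 5
  expect_equal(mean(b1$gcamp_mean[during]), 2, tolerance = 0.05)
  expect_equal(mean(b1$cbv_mean[during]), 1, tolerance = 0.05)
  # constant signal -> all bin averages are zero after baselining
  flat <- structure(list(gcamp_z = rep(1, n), cbv_z = rep(1, n),
                         sample_rate = fs),
                    class = "corrected_photometry")
  out_flat <- event_triggered_photometry(flat, moving)
  for (b in out_flat) if (!is.null(b)) {
    expect_true(all(abs(b$gcamp_mean) < 1e-12))
  }
})
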