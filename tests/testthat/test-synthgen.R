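# Generators: determinism, ground-truth self-consistency, input contracts.

test_that("generators are pure functions of their arguments and seed", {
  expect_identical(make_pial_movie(rep(20, 3), seed = 4)$frames,
                   make_pial_movie(rep(20, 3), seed = 4)$frames)
  expect_false(identical(make_pial_movie(rep(20, 3), seed = 4)$frames,
                         make_pial_movie(rep(20, 3), seed = 5)$frames))
  expect_identical(make_linescan(2, seed = 7, n_lines = 64)$image,
                   make_linescan(2, seed = 7, n_lines = 64)$image)
  b <- rbind(c(2, 9))
  expect_identical(make_locomotion_trace(b, 15, seed = 3)$velocity,
                   make_locomotion_trace(b, 15, seed = 3)$velocity)
  m <- rep(c(FALSE, TRUE), each = 1000)
  expect_identical(make_lfp(m, sample_rate = 1000, seed = 2)$samples,
                   make_lfp(m, sample_rate = 1000, seed = 2)$samples)
  expect_identical(make_cohort(-0.25, 0.05, 0.05, seed = 11),
                   make_cohort(-0.25, 0.05, 0.05, seed = 11))
  # RNG state of the session is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_pial_movie(rep(10, 2), seed = 1))
  expect_identical(runif(1), before)
})

test_that("invalid generator parameters are rejected", {
  expect_error(make_pial_movie(c(20, -1)), "positive")
  expect_error(make_pial_movie(rep(20, 2), pixel_size = 0), "positive")
  expect_error(make_pial_movie(rep(20, 2), frame_rate = -8), "positive")
  expect_error(make_locomotion_trace(rbind(c(5, 3)), 10), "offsets")
  expect_error(make_locomotion_trace(rbind(c(1, 5), c(4, 8)), 10),
               "non-overlapping")
  expect_error(make_photometry(1:10, 1:10,
                               bleach_params = c(a1 = 1, tau1 = -1, a2 = 0,
                                                 tau2 = 10, offset = 0)),
               "positive")
})

test_that("lumen shapes carry exact analytic areas", {
  expect_equal(lumen_area_px2(lumen_shape(10, 10)), 100 * pi,
               tolerance = 1e-6)
  expect_equal(lumen_area_px2(lumen_shape(10, 5)), 50 * pi,
               tolerance = 1e-6)
  # rotation leaves the analytic area untouched
  areas <- vapply(seq(0, pi, length.out = 7), function(phi)
    lumen_area_px2(lumen_shape(10, 5, phi)), numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 1e-10)
  mv <- make_penetrating_movie(lapply(seq(0, 1.5, by = 0.5), function(phi)
    lumen_shape(10, 5, phi)), snr = Inf, pixel_size = 1)
  expect_lt(diff(range(mv$ground_truth$area_px2)), 1e-8)
})

test_that("rendered images match their analytic ground truth within 2%", {
  # brute-force pixel count on the noiseless rendered frame vs analytic
  for (sh in list(lumen_shape(10, 10), lumen_shape(10, 5, 0.7),
                  lumen_shape(8, 8, 0, fourier = list(list(k = 3,
                                                           eps = 0.08,
                                                           phase = 1))))) {
    mv <- make_penetrating_movie(sh, snr = Inf, pixel_size = 1,
                                 psf_sigma_px = 0)
    frame <- mv$frames[1, , ]
    counted <- sum(frame > (min(frame) + max(frame)) / 2)
    expect_equal(counted, lumen_area_px2(sh), tolerance = 0.02)
  }
  # pial movie: noiseless FWHM of the rendered profile equals the diameter
  mv <- make_pial_movie(20, pixel_size = 0.5, snr = Inf)
  prof <- mv$frames[1, 1, ]
  expect_equal(fwhm_profile_width(prof, 0.5), 20, tolerance = 0.5 / 20)
})

test_that("linescan streaks advance at the programmed slope", {
  # 2 mm/s at 0.5 um/px and 2 kHz lines = 2 px per line
  ls <- make_linescan(2, pixel_size = 0.5, line_rate = 2000,
                      particle_density = 0.02, n_lines = 20, seed = 3)
  pos <- apply(ls$image[1:10, ], 1, which.min)
  steps <- diff(pos)
  steps <- steps[abs(steps) < 50]          # ignore wrap-around jumps
  expect_equal(mean(steps), 2, tolerance = 0.26)
  # v = 0: streaks are vertical (constant position across lines)
  ls0 <- make_linescan(0, n_lines = 32, seed = 3)
  expect_identical(ls0$image[1, ], ls0$image[32, ])
  # negated velocity mirrors the streak slope
  lsp <- make_linescan(1.5, n_lines = 64, seed = 5)
  lsn <- make_linescan(-1.5, n_lines = 64, seed = 5)
  expect_equal(dim(lsp$image), dim(lsn$image))
})

test_that("locomotion traces are silent at rest and jittery when moving", {
  tr <- make_locomotion_trace(rbind(c(3, 10)), 15, noise_sd = 0.5, seed = 1)
  t <- (seq_along(tr$velocity) - 1) / tr$sample_rate
  expect_true(all(tr$velocity[t < 3 | t > 10] == 0))
  expect_gt(sd(tr$velocity[t > 4 & t < 9]), 0.2)
  expect_equal(mean(tr$velocity[t > 4 & t < 9]), 10, tolerance = 0.05)
})

test_that("cohort tables obey the mixed-effects generating model", {
  co <- make_cohort(0, 0, 0, seed = 1)
  expect_equal(co$d_treatment_um, co$d_vehicle_um)
  co2 <- make_cohort(-0.25, 0, 0, seed = 2)
  expect_equal(co2$d_treatment_um / co2$d_vehicle_um - 1,
               rep(-0.25, nrow(co2)))
  gt <- attr(make_cohort(-0.1, 0.05, 0.02, seed = 3), "ground_truth")
  expect_length(gt$beta_a, 6)
})
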