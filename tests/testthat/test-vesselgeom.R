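# FWHM profiling, TiRS segmentation, and diameter-trace conditioning.

test_that("FWHM matches analytic widths of box and Gaussian profiles", {
  # box, width 10 px at 0.5 um/px -> 5 um
  prof <- c(rep(0, 5), rep(1, 10), rep(0, 5))
  expect_equal(fwhm_profile_width(prof, 0.5), 5, tolerance = 1e-8)
  # Gaussian, sigma 4 px -> 2 sqrt(2 ln 2) * 4 = 9.419 px
  x <- 1:81
  g <- exp(-(x - 41)^2 / (2 * 16))
  expect_lt(abs(fwhm_profile_width(g, 1) - 2 * sqrt(2 * log(2)) * 4), 0.5)
  # analytic widths across sizes, within half a pixel
  for (w in c(4, 10, 22, 40)) {
    box <- c(rep(0, 25), rep(1, w), rep(0, 25))
    expect_lt(abs(fwhm_profile_width(box, 1) - w), 0.5)
  }
  for (s in c(2, 5, 10)) {
    x <- seq_len(24 * s)
    g <- exp(-(x - 12 * s)^2 / (2 * s^2))
    expect_lt(abs(fwhm_profile_width(g, 1) - 2 * sqrt(2 * log(2)) * s), 0.5)
  }
})

test_that("FWHM rejects flat and edge-truncated profiles", {
  expect_error(fwhm_profile_width(rep(0, 50)), "no-vessel")
  expect_error(fwhm_profile_width(rep(3, 50)), "no-vessel")
  # peak at the edge: no crossing on one side
  expect_error(fwhm_profile_width(c(rep(0, 20), seq(0, 1, 0.1))),
               "edge-truncation")
})

test_that("FWHM takes the crossing pair bracketing the global peak", {
  # a side lobe must not widen the measurement
  main <- 10 * exp(-((1:101) - 51)^2 / (2 * 9))
  lobe <- 4 * exp(-((1:101) - 20)^2 / (2 * 4))
  w <- fwhm_profile_width(main + lobe, 1)
  expect_lt(abs(w - 2 * sqrt(2 * log(2)) * 3), 0.5)
})

test_that("diameter traces recover the programmed vessel width", {
  mv <- make_pial_movie(rep(20, 12), pixel_size = 0.5, snr = 10, seed = 2)
  tr <- fwhm_diameter_trace(mv)
  expect_s3_class(tr, "diameter_trace")
  expect_equal(mean(tr$values), 20, tolerance = 0.02)
  # a blanked frame is flagged missing, the rest unaffected
  mv$frames[5, , ] <- 0
  tr2 <- fwhm_diameter_trace(mv)
  expect_true(tr2$missing_mask[5])
  expect_true(is.na(tr2$values[5]))
  expect_equal(tr2$values[-5], tr$values[-5], tolerance = 1e-12)
  # segment length outside 1-3 um is clamped with a warning
  expect_warning(fwhm_diameter_trace(mv, segment_length_um = 5), "clamp")
  expect_error(fwhm_diameter_trace(
    structure(c(mv[setdiff(names(mv), "axis_line")], list(axis_line = NULL)),
              class = "vessel_movie")), "axis_line")
})

test_that("TiRS recovers analytic areas of noiseless disks and ellipses", {
  for (r in c(5, 10, 20)) {
    mv <- make_penetrating_movie(lumen_shape(r, r), snr = Inf,
                                 pixel_size = 1)
    m <- tirs_area(mv$frames[1, , ])
    expect_equal(m$area, pi * r^2, tolerance = 0.05)
    expect_equal(m$diameter, 2 * r, tolerance = 0.03)
  }
  mv <- make_penetrating_movie(lumen_shape(10, 5, 0.6), snr = Inf,
                               pixel_size = 1)
  expect_equal(tirs_area(mv$frames[1, , ])$area, 50 * pi, tolerance = 0.05)
})

test_that("TiRS area is rotation invariant", {
  areas <- vapply(seq(0, 150, by = 30), function(deg) {
    mv <- make_penetrating_movie(lumen_shape(10, 5, deg * pi / 180),
                                 snr = Inf, pixel_size = 1)
    tirs_area(mv$frames[1, , ])$area
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.03)
})

test_that("TiRS errors on empty input and honors the ROI contract", {
  expect_error(tirs_area(matrix(0, 32, 32)), "no-vessel")
  mv <- make_penetrating_movie(lumen_shape(8, 8), snr = Inf, pixel_size = 1)
  expect_error(tirs_area(mv$frames[1, , ], roi = c(0, 65, 1, 64)), "roi")
  ok <- tirs_area(mv$frames[1, , ], roi = c(10, 55, 10, 55))
  expect_equal(ok$area, 64 * pi, tolerance = 0.05)
})

test_that("FWHM and TiRS agree on a circular lumen", {
  mv <- make_penetrating_movie(lumen_shape(12, 12), snr = Inf,
                               pixel_size = 1)
  frame <- mv$frames[1, , ]
  d_tirs <- tirs_area(frame)$diameter
  prof <- colMeans(frame[31:34, ])
  d_fwhm <- fwhm_profile_width(prof, 1)
  expect_equal(d_fwhm, d_tirs, tolerance = 0.05)
})

test_that("estimated diameter increases with true width on clean input", {
  widths <- c(6, 10, 14, 18, 24)
  est <- vapply(widths, function(w) {
    mv <- make_pial_movie(w, pixel_size = 0.5, snr = Inf)
    fwhm_diameter_trace(mv)$values[1]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("equivalent diameter is the circle-equivalent conversion", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(100 * pi), 20)
  expect_identical(equivalent_diameter(0), 0)
  expect_error(equivalent_diameter(-1), "non-negative")
})

test_that("despiking replaces motion artifacts by local interpolation", {
  # 3 um jump at 8 Hz = 24 um/s > 16 um/s
  tr <- new_trace <- structure(
    list(values = c(20, 20, 23, 20), frame_rate = 8,
         missing_mask = rep(FALSE, 4), despiked_mask = rep(FALSE, 4)),
    class = "diameter_trace")
  out <- despike_trace(tr)
  expect_equal(out$values, c(20, 20, 20, 20))
  expect_true(out$despiked_mask[3])
  # sub-threshold slow modulation is untouched
  t <- seq(0, 10, by = 1 / 8)
  slow <- structure(list(values = 20 + 2 * sin(2 * pi * 0.1 * t),
                         frame_rate = 8,
                         missing_mask = rep(FALSE, length(t)),
                         despiked_mask = rep(FALSE, length(t))),
                    class = "diameter_trace")
  expect_equal(despike_trace(slow)$values, slow$values)
  # two consecutive spikes interpolate across the same gap
  tr2 <- structure(list(values = c(20, 26, 14, 20), frame_rate = 8,
                        missing_mask = rep(FALSE, 4),
                        despiked_mask = rep(FALSE, 4)),
                   class = "diameter_trace")
  out2 <- despike_trace(tr2)
  expect_equal(out2$values, c(20, 20, 20, 20), tolerance = 1e-10)
  expect_error(despike_trace(structure(list(values = c(1, 2),
                                            frame_rate = 8,
                                            missing_mask = c(FALSE, FALSE)),
                                       class = "diameter_trace")),
               "3 frames")
})

test_that("despiking is idempotent", {
  vals <- c(20, 20, 25, 20, 20, 14, 20)
  tr <- structure(list(values = vals, frame_rate = 8,
                       missing_mask = rep(FALSE, 7),
                       despiked_mask = rep(FALSE, 7)),
                  class = "diameter_trace")
  once <- despike_trace(tr)
  twice <- despike_trace(once)
  expect_equal(twice$values, once$values)
  expect_false(any(twice$despiked_mask))
})

test_that("median filtering matches direct medians and edge handling", {
  tr <- structure(list(values = rep(7, 10), frame_rate = 8,
                       missing_mask = rep(FALSE, 10),
                       despiked_mask = rep(FALSE, 10)),
                  class = "diameter_trace")
  expect_equal(median_filter_trace(tr)$values, rep(7, 10))
  imp <- tr; imp$values[5] <- 100
  expect_equal(median_filter_trace(imp)$values, rep(7, 10))
  mono <- tr; mono$values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(median_filter_trace(mono)$values, mono$values)
  # twice equals once on piecewise-constant traces
  pc <- tr; pc$values <- c(rep(2, 5), rep(9, 5))
  once <- median_filter_trace(pc)
  expect_equal(median_filter_trace(once)$values, once$values)
  expect_error(median_filter_trace(tr, order = 4), "odd")
})
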