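# Locomotion binarization, segmentation, triggered averaging and derived
# metrics.

test_that("constant velocity has zero acceleration and is stationary", {
  mv <- binarize_locomotion(rep(3, 5000), sample_rate = 1000)
  # away from the forward-backward filter's boundary transients, whose
  # tails stay above the 1e-5 threshold for about a second
  expect_true(all(!mv[2000:3000]))
  expect_error(binarize_locomotion(rep(0, 100), sample_rate = 15),
               "invalid-rate")
})

test_that("a velocity step marks movement only near the transition", {
  v <- c(rep(0, 5000), rep(8, 5000))
  mv <- binarize_locomotion(v, sample_rate = 1000, accel_threshold = 0.3)
  moving_idx <- which(mv[500:9500]) + 499   # interior, past edge transients
  expect_true(all(abs(moving_idx - 5000) < 1000))
  expect_gt(length(moving_idx), 0)
})

test_that("bout onsets are recovered within 0.2 s across seeds", {
  bouts <- rbind(c(10, 18), c(30, 42))
  errs <- vapply(1:20, function(s) {
    tr <- make_locomotion_trace(bouts, 60, seed = s)
    mv <- binarize_locomotion(tr, accel_threshold = 0.3)
    ev <- extract_lta_events(mv, tr$sample_rate)
    if (nrow(ev) != 2) return(Inf)
    max(abs(ev[, "onset_s"] - bouts[, 1]))
  }, numeric(1))
  expect_lt(max(errs), 0.2)
  # at the ultra-low default threshold, the raw mask covers essentially
  # all genuine bout samples
  tr <- make_locomotion_trace(bouts, 60, seed = 1)
  mv_low <- binarize_locomotion(tr)
  truth <- bout_mask(bouts, 60, tr$sample_rate)
  expect_gt(mean(mv_low[truth]), 0.95)
  # at the onset-calibrated threshold, merged events still span the bouts
  mv <- binarize_locomotion(tr, accel_threshold = 0.3)
  ev <- locomotion_events(mv, tr$sample_rate)
  evmask <- bout_mask(ev, 60, tr$sample_rate)
  expect_gt(mean(evmask[truth]), 0.95)
})

test_that("nearby moving runs merge into a single event", {
  fs <- 1000
  m <- bout_mask(rbind(c(2, 6), c(6.5, 10)), 15, fs)   # 0.5 s gap
  expect_identical(nrow(locomotion_events(m, fs)), 1L)
  m2 <- bout_mask(rbind(c(2, 6), c(8, 12)), 15, fs)    # 2 s gap
  expect_identical(nrow(locomotion_events(m2, fs)), 2L)
})

test_that("stationary periods honor the 2 s / 1 s buffers", {
  fs <- 1000
  # all-still trace: one period spanning the trace
  allq <- find_stationary_periods(rep(FALSE, 30 * fs), fs)
  expect_equal(allq[1, ], c(start_s = 0, end_s = 30 - 1 / fs),
               tolerance = 1e-6)
  # 10 s still between two bouts -> 7 s period
  m <- bout_mask(rbind(c(5, 10), c(20, 25)), 30, fs)
  per <- find_stationary_periods(m, fs)
  mid <- per[per[, 1] > 10 & per[, 2] < 20, , drop = FALSE]
  expect_identical(nrow(mid), 1L)
  expect_equal(unname(mid[1, 1]), 12, tolerance = 1e-3)
  expect_equal(unname(mid[1, 2]), 19, tolerance = 1e-3)
  # 2.5 s still gap leaves nothing after the buffers
  m2 <- bout_mask(rbind(c(5, 10), c(12.5, 18)), 30, fs)
  per2 <- find_stationary_periods(m2, fs)
  expect_false(any(per2[, 1] > 10 & per2[, 2] < 12.5))
})

test_that("qualifying events need > 5 s duration and 2 s prior quiet", {
  fs <- 1000
  qual <- extract_lta_events(bout_mask(rbind(c(5, 13)), 30, fs), fs)
  expect_identical(nrow(qual), 1L)
  short <- extract_lta_events(bout_mask(rbind(c(5, 9)), 30, fs), fs)
  expect_identical(nrow(short), 0L)
  crowded <- extract_lta_events(
    bout_mask(rbind(c(2, 3.3), c(4.5, 13)), 30, fs), fs)
  expect_identical(nrow(crowded), 0L)
})

test_that("basal value averages the stationary samples", {
  fs <- 8
  per <- matrix(c(0, 10), 1, 2)
  expect_equal(basal_value(rep(20, 100), fs, per), 20)
  # dilation confined to a bout leaves the basal at the quiet plateau
  t <- (0:239) / fs
  x <- 20 + 5 * (t > 15 & t < 20)
  per2 <- rbind(c(0, 14), c(23, 29.9))
  expect_equal(basal_value(x, fs, per2), 20)
  expect_error(basal_value(rep(1, 10), fs, matrix(numeric(0), 0, 2)),
               "stationary")
})

test_that("triggered averages normalize and aggregate event segments", {
  fs <- 8
  t <- (0:799) / fs
  x <- rep(20, length(t))
  for (on in c(20, 50, 80)) x[t >= on & t <= on + 6] <- 23
  ev <- cbind(onset_s = c(20, 50, 80), offset_s = c(26, 56, 86))
  lta <- locomotion_triggered_average(x, ev, 20, sample_rate = fs)
  expect_identical(lta$n_events, 3L)
  expect_equal(max(lta$sem), 0)
  expect_equal(mean(lta$mean[lta$rel_time < 0]), 1, tolerance = 1e-9)
  expect_equal(mean(lta$mean[lta$rel_time > 1 & lta$rel_time < 5]),
               23 / 20, tolerance = 1e-9)
  # flat trace normalized by its own basal is identically 1
  flat <- locomotion_triggered_average(rep(20, length(t)), ev, 20,
                                       sample_rate = fs)
  expect_true(all(abs(flat$mean - 1) < 1e-12))
  expect_equal(evoked_amplitude(flat), 0)
  expect_error(locomotion_triggered_average(x, cbind(795, 800), 20,
                                            sample_rate = fs), "inside")
})

test_that("evoked amplitude averages 3-4 s after onset, in percent", {
  lta <- structure(list(rel_time = seq(-2, 10, by = 0.125),
                        mean = rep(1, 97), sem = rep(0, 97), n_events = 1L,
                        normalization_reference = 20),
                   class = "triggered_average")
  expect_equal(evoked_amplitude(lta), 0)
  lta$mean[lta$rel_time >= 3 & lta$rel_time <= 4] <- 1.2
  expect_equal(evoked_amplitude(lta), 20)
})

test_that("onset time is exact on noiseless ramps", {
  fs <- 8
  rel <- seq(-2, 10, by = 1 / fs)
  for (ramp_end in c(2, 3, 5)) {
    m <- rep(1, length(rel))
    rising <- rel >= 1 & rel <= ramp_end
    m[rising] <- 1 + 0.2 * (rel[rising] - 1) / (ramp_end - 1)
    m[rel > ramp_end] <- 1.2
    lta <- structure(list(rel_time = rel, mean = m,
                          sem = rep(0, length(rel)), n_events = 1L,
                          normalization_reference = 20),
                     class = "triggered_average")
    o <- onset_time(lta)
    expect_false(o$degenerate)
    expect_lt(abs(o$onset_s - 1), 1 / fs)
  }
  flat <- structure(list(rel_time = rel, mean = rep(1, length(rel)),
                         sem = rep(0, length(rel)), n_events = 1L,
                         normalization_reference = 20),
                    class = "triggered_average")
  expect_error(onset_time(flat), "peak")
  # instantaneous step: degenerate, first supra-20% sample
  step <- flat
  step$mean[rel > 3] <- 1.3
  o2 <- onset_time(step)
  expect_true(o2$degenerate)
  expect_equal(o2$onset_s, rel[rel > 3][1])
})

test_that("onset time tolerates noise on the ramp", {
  fs <- 8
  rel <- seq(-2, 10, by = 1 / fs)
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    m <- rep(1, length(rel))
    rising <- rel >= 1 & rel <= 3
    m[rising] <- 1 + 0.2 * (rel[rising] - 1) / 2
    m[rel > 3] <- 1.2
    m <- m + rnorm(length(m), 0, 0.004)
    lta <- structure(list(rel_time = rel, mean = m,
                          sem = rep(0, length(rel)), n_events = 1L,
                          normalization_reference = 20),
                     class = "triggered_average")
    abs(onset_time(lta)$onset_s - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.2)
})

test_that("the locomotion-induced dilation metric follows its convention", {
  expect_equal(locomotion_induced_metric(0.90, 1.05), 15)
  expect_equal(locomotion_induced_metric(1.10, 1.15), 5)
  expect_equal(locomotion_induced_metric(1, 1), 0)
  # ties the two reporting conventions together
  for (b in c(0.9, 1, 1.1)) for (e in c(0.95, 1.05, 1.2)) {
    rel_to_vehicle <- (e - 1) * 100
    expect_equal(locomotion_induced_metric(b, e) + (b - 1) * 100,
                 rel_to_vehicle, tolerance = 1e-12)
  }
})
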