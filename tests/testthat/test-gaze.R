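test_that("gap interpolation fills short gaps and leaves long ones masked", {
  fs <- 100
  ramp <- seq(0, 10, length.out = 1001)
  x <- ramp
  x[300:309] <- NaN                               # 100 ms gap
  s <- interpolate_gaps(pupil_series(x, fs))
  expect_true(all(s$valid[300:309]))
  expect_lt(max(abs(s$diameter - ramp)), 1e-6)    # spline reproduces a line
  x2 <- ramp; x2[300:360] <- NaN                  # 610 ms gap
  s2 <- interpolate_gaps(pupil_series(x2, fs))
  expect_false(any(s2$valid[300:360]))
  # no gaps: identity
  s3 <- interpolate_gaps(pupil_series(ramp, fs))
  expect_identical(s3$diameter, ramp)
  # boundary gap: nearest-valid fill with a flag
  x4 <- ramp; x4[1:20] <- NaN
  expect_message(s4 <- interpolate_gaps(pupil_series(x4, fs)), "boundary")
  expect_true(all(is.finite(s4$diameter[1:20])))
})

test_that("rolling median removes spikes and preserves monotone series", {
  fs <- 500                                        # 20 ms window = 11 samples
  x <- rep(3, 200); x[100] <- 9
  s <- median_roll(pupil_series(x, fs), 20)
  expect_equal(s$diameter, rep(3, 200))
  ramp <- seq(1, 2, length.out = 200)
  sr <- median_roll(pupil_series(ramp, fs), 20)
  expect_equal(sr$diameter, ramp, tolerance = 1e-12)
})

test_that("physiological clipping masks without clamping", {
  x <- c(0.5, 3, 9.5, 4)
  s <- clip_physiological(pupil_series(x, 10))
  expect_identical(s$valid, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(is.nan(s$diameter[1]) && is.nan(s$diameter[3]))
  y <- c(2, 3, 4)
  expect_identical(clip_physiological(pupil_series(y, 10))$diameter, y)
})

test_that("median pupil over fixations uses only valid in-fixation samples", {
  fs <- 10
  x <- rep(3, 50)
  fx <- data.frame(onset_s = 1, offset_s = 2)
  expect_equal(median_pupil_fixations(pupil_series(x, fs), fx), 3)
  # {2, 3, 10} with 10 masked -> 2.5
  x2 <- c(2, 3, 10, rep(100, 7))
  v2 <- c(TRUE, TRUE, FALSE, rep(TRUE, 7))
  fx2 <- data.frame(onset_s = 0, offset_s = 0.25)
  expect_equal(median_pupil_fixations(pupil_series(x2, 10, v2), fx2), 2.5)
  # samples outside fixations are ignored
  x3 <- c(rep(3, 5), rep(50, 45))
  fx3 <- data.frame(onset_s = 0, offset_s = 0.4)
  expect_equal(median_pupil_fixations(pupil_series(x3, 10), fx3), 3)
  expect_error(median_pupil_fixations(
    pupil_series(rep(NaN, 50), fs), fx), "no valid")
})

test_that("IPA counts injected discontinuities and ignores smooth signals", {
  fs <- 250; t <- (0:2499) / fs
  smooth <- 3.5 + 0.2 * sin(2 * pi * 0.1 * t)
  expect_equal(ipa(pupil_series(smooth, fs)), 0)
  # injection recovery at 1 event/s over 50 seeds
  p <- gaze_params(duration_s = 10, fs = 250, discontinuity_rate = 1,
                   pupil_noise_sd = 0.005, blink_rate = 0)
  rates <- vapply(1:50, function(i)
    ipa(preprocess_pupil(generate_gaze_block(p, seed = i))), 0)
  expect_lt(abs(mean(rates) - 1), 0.3)
})

test_that("IPA is invariant to uniform amplitude scaling", {
  p <- gaze_params(duration_s = 10, fs = 250, discontinuity_rate = 1,
                   pupil_noise_sd = 0.005, blink_rate = 0)
  for (i in 1:5) {
    b <- generate_gaze_block(p, seed = i)
    s1 <- pupil_series(b$pupil_mm, b$fs)
    s2 <- pupil_series(b$pupil_mm * 2, b$fs)
    expect_equal(ipa(s1), ipa(s2))
  }
})

test_that("IPA estimates are monotone in the injected rate", {
  means <- vapply(c(0, 0.5, 1, 2), function(r) {
    p <- gaze_params(duration_s = 10, fs = 250, discontinuity_rate = r,
                     pupil_noise_sd = 0.005, blink_rate = 0)
    mean(vapply(1:25, function(i)
      ipa(preprocess_pupil(generate_gaze_block(p, seed = i))), 0))
  }, 0)
  expect_identical(order(means), 1:4)   # Spearman rho = 1 on the grid
})

test_that("gaze dispersion matches hand-computed cases and invariances", {
  one <- data.frame(x = c(1, 1), y = c(2, 2), duration_s = c(1, 2))
  expect_equal(gaze_dispersion(one), 0)
  two <- data.frame(x = c(0, 2), y = c(0, 0), duration_s = c(1, 1))
  expect_equal(gaze_dispersion(two), 1)
  wt <- data.frame(x = c(0, 4), y = c(0, 0), duration_s = c(1, 3))
  expect_equal(gaze_dispersion(wt), sqrt(3))
  expect_message(s1 <- gaze_dispersion(
    data.frame(x = 1, y = 1, duration_s = 1)), "single fixation")
  expect_equal(s1, 0)
  # translation / rotation invariance, linear scaling
  set.seed(1)
  fx <- data.frame(x = rnorm(10), y = rnorm(10),
                   duration_s = runif(10, 0.1, 1))
  d0 <- gaze_dispersion(fx)
  shifted <- fx; shifted$x <- fx$x + 5; shifted$y <- fx$y - 3
  expect_equal(gaze_dispersion(shifted), d0)
  th <- 0.7
  rot <- fx
  rot$x <- cos(th) * fx$x - sin(th) * fx$y
  rot$y <- sin(th) * fx$x + cos(th) * fx$y
  expect_equal(gaze_dispersion(rot), d0)
  scaled <- fx; scaled$x <- 3 * fx$x; scaled$y <- 3 * fx$y
  expect_equal(gaze_dispersion(scaled), 3 * d0)
})

test_that("blink rate and baseline correction are simple and exact", {
  expect_equal(blink_rate(data.frame(onset_s = numeric(0)), 100), 0)
  expect_equal(blink_rate(30, 300), 0.1)
  # pooled rate = duration-weighted mean of rates
  r1 <- blink_rate(10, 100); r2 <- blink_rate(50, 400)
  expect_equal(blink_rate(60, 500), (100 * r1 + 400 * r2) / 500)
  expect_equal(baseline_correct(3.4, 3.1), 0.3)
  expect_equal(baseline_correct(2, 2), 0)
  expect_equal(baseline_correct(1, 5), -baseline_correct(5, 1))
  expect_error(baseline_correct(Inf, 1), "finite")
})

test_that("preprocessing is idempotent on clean series", {
  fs <- 250
  # clean = gap-free, spike-free, in-range; smooth drift
  t <- (0:999) / fs
  x <- 3.5 + 0.3 * sin(2 * pi * 0.2 * t)
  s1 <- preprocess_pupil(pupil_series(x, fs))
  s2 <- preprocess_pupil(s1)
  expect_equal(s1$diameter, s2$diameter, tolerance = 1e-12)
  expect_identical(s1$valid, s2$valid)
})

test_that("gaze CSV round trip preserves the block", {
  b <- generate_gaze_block(gaze_params(duration_s = 5), seed = 1)
  stem <- file.path(tempdir(), "gaze_block")
  write_gaze_csv(b, stem)
  b2 <- read_gaze_csv(stem, fs = b$fs)
  expect_equal(b2$pupil_mm, b$pupil_mm)
  expect_equal(b2$fixations$onset_s, b$fixations$onset_s)
  expect_identical(nrow(b2$blinks), nrow(b$blinks))
})
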