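test_that("zero-phase Butterworth passes DC and low bands, kills high bands", {
  x <- rep(3.2, 200)
  expect_equal(butterworth_lowpass(x, 6, 100), x, tolerance = 1e-9)

  t <- seq(0, 2, by = 0.01)
  s1 <- sin(2 * pi * 1 * t)
  f1 <- butterworth_lowpass(s1, 6, 100)
  expect_gt(max(abs(f1[50:150])) / max(abs(s1[50:150])), 0.99)

  s40 <- sin(2 * pi * 40 * t)
  f40 <- butterworth_lowpass(s40, 6, 100)
  expect_lt(max(abs(f40[50:150])) / max(abs(s40[50:150])), 0.05)

  expect_error(butterworth_lowpass(s1, cutoff = 6, rate = 10),
               class = "caninegait_invalid_input")
  expect_error(butterworth_lowpass(c(1, NA, 3), 6, 100),
               class = "caninegait_invalid_input")
})

quintic_markers <- function(n = 40) {
  t <- seq(0, (n - 1)) / 100
  # quintic polynomial trajectories are reproduced exactly by the fill
  tibble::tibble(
    time = rep(t, each = 1), marker = "m1",
    x = 1 + 2 * t + 3 * t^2 - t^3 + 0.5 * t^4 - 0.2 * t^5,
    y = 2 - t + t^2 + 0.3 * t^5,
    z = 0.5 + t^3,
    visible = TRUE
  )
}

test_that("quintic gap fill recovers polynomial trajectories exactly", {
  mk <- quintic_markers()
  expect_equal(fill_gaps_quintic(mk), mk, ignore_attr = TRUE)

  gap <- 15:17
  mk2 <- mk
  mk2$x[gap] <- NA; mk2$y[gap] <- NA; mk2$z[gap] <- NA
  mk2$visible[gap] <- FALSE
  filled <- fill_gaps_quintic(mk2)
  expect_true(attr(filled, "trial_valid"))
  expect_lt(max(abs(filled$x - mk$x)), 1e-8)
  expect_lt(max(abs(filled$y - mk$y)), 1e-8)
  expect_true(all(filled$visible))
})

test_that("long and boundary gaps are left unfilled and flag the trial", {
  mk <- quintic_markers()
  gap <- 15:19                       # 5 frames: not fillable
  mk$x[gap] <- NA; mk$y[gap] <- NA; mk$z[gap] <- NA
  mk$visible[gap] <- FALSE
  filled <- fill_gaps_quintic(mk)
  expect_false(attr(filled, "trial_valid"))
  expect_true(all(is.na(filled$x[gap])))
  gaps <- attr(filled, "unfilled_gaps")
  expect_equal(gaps$length, 5L)
  expect_equal(gaps$reason, "too_long")

  mk2 <- quintic_markers()
  mk2$x[1:2] <- NA; mk2$visible[1:2] <- FALSE
  filled2 <- fill_gaps_quintic(mk2)
  expect_false(attr(filled2, "trial_valid"))
  expect_equal(attr(filled2, "unfilled_gaps")$reason, "insufficient_support")
})

test_that("gait cycles are segmented at threshold crossings with debounce", {
  rate <- 1000
  t <- seq(0, 1.4, by = 1 / rate)
  fy <- ifelse((t >= 0.1 & t < 0.5) | (t >= 0.8 & t < 1.2), 30, 0)
  cyc <- segment_gait_cycle(tibble::tibble(time = t, fy = fy), threshold = 5)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$start_time, 0.1)
  expect_equal(cyc$end_time, 0.8)
  expect_equal(cyc$stance_fraction, (0.5 - 0.1) / (0.8 - 0.1),
               tolerance = 0.01)

  # chatter blips shorter than the 50 ms debounce do not create cycles
  fy_chat <- fy
  fy_chat[t > 0.6 & t < 0.62] <- 30
  cyc2 <- segment_gait_cycle(tibble::tibble(time = t, fy = fy_chat),
                             threshold = 5)
  expect_equal(nrow(cyc2), 1)
  expect_equal(cyc2$end_time, 0.8)

  expect_error(segment_gait_cycle(tibble::tibble(time = t, fy = fy),
                                  threshold = 0),
               class = "caninegait_invalid_input")
  expect_error(segment_gait_cycle(tibble::tibble(time = t, fy = fy * 0),
                                  threshold = 5),
               class = "caninegait_no_contact")
})

test_that("synthetic walking GRF segments at the designed stance fraction", {
  trial <- cached_trial(seed = 1, noise_sd_mm = 0)
  bw <- trial$spec$body_mass_kg * 9.81
  cyc <- segment_gait_cycle(trial$grf, threshold = 0.02 * bw)
  expect_lt(abs(cyc$stance_fraction[1] - 0.6), 0.05)
  expect_lt(abs(cyc$end_time[1] - cyc$start_time[1] -
                  trial$spec$cycle_duration_s), 0.03)
})

test_that("cycle resampling interpolates linearly and keeps endpoints", {
  expect_equal(resample_cycle(rep(2, 10), n = 100), rep(2, 100))
  ramp <- resample_cycle(tibble::tibble(time = 0:9, v = 2 * (0:9)), n = 100)
  expect_equal(ramp$v[1], 0)
  expect_equal(ramp$v[100], 18)
  expect_equal(ramp$v, approx(0:9, 2 * (0:9),
                              xout = seq(0, 9, length.out = 100))$y)
  # resampling 100 points onto 100 points is the identity
  s <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(resample_cycle(s, n = 100), s, tolerance = 1e-12)
  expect_error(resample_cycle(1), class = "caninegait_invalid_input")
})

test_that("filtering and resampling commute for band-limited signals", {
  t <- seq(0, 0.99, by = 0.01)
  ang <- 20 + 10 * sin(2 * pi * 1.5 * t) + 3 * cos(2 * pi * 3 * t)
  a <- resample_cycle(butterworth_lowpass(ang, 6, 100), n = 100)
  b <- butterworth_lowpass(resample_cycle(ang, n = 100), 6,
                           rate = 100 / 0.99)
  expect_lt(max(abs(a - b)), 0.5)
})
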