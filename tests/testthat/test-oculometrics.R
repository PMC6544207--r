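test_that("blink-family metrics follow their definitions", {
  # 20 blinks in 200 s -> BF = 0.1 Hz
  on <- seq(0, by = 10, length.out = 20)
  ev <- make_event_sequence(rep("blink", 20), on, on + 0.15)
  bm <- blink_metrics(ev, 200, closed_samples = 900, open_samples = 8100)
  expect_equal(bm$BF, 0.1)
  expect_equal(bm$BD, 0.15, tolerance = 1e-9)
  # PERCLOS per the closed/opened convention
  expect_equal(bm$PERCLOS, 100 * 900 / 8100, tolerance = 1e-9)

  # IBI excludes gaps > 20 s: blinks at 0, 0.5, 30 (0.1-s durations)
  ev2 <- make_event_sequence(rep("blink", 3), c(0, 0.5, 30),
                             c(0.1, 0.6, 30.1))
  bm2 <- blink_metrics(ev2, 60, 0, 100)
  expect_equal(bm2$IBI, 0.4, tolerance = 1e-9)  # gap offset->onset
  # the same pair also makes one double blink (gap < 700 ms)
  expect_equal(bm2$DBF, 1 / 60, tolerance = 1e-9)

  # long blinks > 200 ms
  ev3 <- make_event_sequence(rep("blink", 4), c(1, 2, 3, 4),
                             c(1.1, 2.3, 3.25, 4.05))
  bm3 <- blink_metrics(ev3, 100, 0, 100)
  expect_equal(bm3$LBF, 2 / 100)
  expect_equal(bm3$LBR, 0.5)

  # no blinks: rates zero, means missing
  bm0 <- blink_metrics(make_event_sequence("fixation", 0, 1), 10, 0, 100)
  expect_equal(bm0$BF, 0)
  expect_true(is.na(bm0$BD) && is.na(bm0$IBI) && is.na(bm0$TBS))
})

test_that("blink gaze-shift and blink-to-saccade latency features", {
  # fixation centers 0 cm and 4 cm apart straddling the blink: shift
  # 2*atan(2/58) deg > 2 deg
  ev <- make_event_sequence(
    c("fixation", "blink", "fixation", "saccade"),
    onset_s = c(0, 1, 1.2, 1.75), offset_s = c(1, 1.2, 1.7, 1.80),
    center_x_cm = c(-2, NA, 2, NA))
  bm <- blink_metrics(ev, 10, 0, 100)
  expect_equal(bm$BGF, 1 / 10)
  expect_equal(bm$BGR, 1)
  # TBS: blink offset 1.2 -> saccade onset 1.75 = 0.55 < 0.7
  expect_equal(bm$TBS, 0.55, tolerance = 1e-9)

  # identical flanking centers: no gaze shift
  ev2 <- make_event_sequence(
    c("fixation", "blink", "fixation"),
    onset_s = c(0, 1, 1.2), offset_s = c(1, 1.2, 1.7),
    center_x_cm = c(1, NA, 1))
  bm2 <- blink_metrics(ev2, 10, 0, 100)
  expect_equal(bm2$BGF, 0)
})

test_that("saccade-family metrics and main-sequence slopes", {
  # exact main sequence v = 50 * A: slope 50, regardless of intercept noise
  amps <- c(2, 4, 6, 8)
  ev <- make_event_sequence(rep("saccade", 4), 1:4, 1:4 + 0.04,
                            amplitude_deg = amps,
                            peak_vel_dps = 50 * amps)
  sm <- saccade_metrics(ev, 200)
  expect_equal(sm$SVA, 50, tolerance = 1e-9)
  expect_equal(sm$SF, 4 / 200)
  expect_equal(sm$SA, 5)
  expect_equal(sm$SPV, 250)

  # SDA on the 3-point closed-form OLS slope
  ev2 <- make_event_sequence(rep("saccade", 3), c(1, 2, 3),
                             c(1.02, 2.03, 3.05),
                             amplitude_deg = c(2, 4, 8),
                             peak_vel_dps = c(100, 200, 400))
  sm2 <- saccade_metrics(ev2, 100)
  expect_equal(sm2$SDA, 0.005, tolerance = 1e-9)

  # 120 saccades in 200 s -> SF 0.6 Hz
  on <- seq(0, by = 1.5, length.out = 120)
  ev3 <- make_event_sequence(rep("saccade", 120), on, on + 0.04,
                             amplitude_deg = 5, peak_vel_dps = 250)
  expect_equal(saccade_metrics(ev3, 200)$SF, 0.6)
  # ISI: constant 1.46-s gaps all exceed 250 ms -> missing
  expect_true(is.na(saccade_metrics(ev3, 200)$ISI))

  # no saccades: everything missing except SF = 0
  sm0 <- saccade_metrics(make_event_sequence("fixation", 0, 1), 10)
  expect_equal(sm0$SF, 0)
  expect_true(is.na(sm0$SPV) && is.na(sm0$SVA))
  # fewer than 3 saccades: slopes missing
  expect_true(is.na(saccade_metrics(
    make_event_sequence(rep("saccade", 2), 1:2, 1:2 + 0.04,
                        amplitude_deg = c(2, 4),
                        peak_vel_dps = c(100, 200)), 10)$SVA))
})

test_that("fixation metrics: dispersion, pairs, long-fixation rate", {
  # centers at the corners of a 2-cm square: OD = sqrt(2)
  ev <- make_event_sequence(rep("fixation", 4), c(0, 2, 4, 6),
                            c(1, 3, 5, 7))
  ev$events$center_x_cm <- c(-1, 1, 1, -1)
  ev$events$center_y_cm <- c(-1, -1, 1, 1)
  fm <- fixation_metrics(ev, NULL, 10)
  expect_equal(fm$OD, sqrt(2), tolerance = 1e-9)
  # durations 1 s each: LFR = 100%
  expect_equal(fm$LFR, 100)

  # mixed durations [0.5, 1.0, 1.2]: LFR = 2/3
  ev2 <- make_event_sequence(rep("fixation", 3), c(0, 1, 3),
                             c(0.5, 2, 4.2))
  ev2$events$center_x_cm <- 0; ev2$events$center_y_cm <- 0
  expect_equal(fixation_metrics(ev2, NULL, 10)$LFR, 200 / 3,
               tolerance = 1e-6)

  # no fixations: FF = 0, the rest missing
  fm0 <- fixation_metrics(make_event_sequence("saccade", 0, 0.05), NULL, 10)
  expect_equal(fm0$FF, 0)
  expect_true(is.na(fm0$FD) && is.na(fm0$OD))
})

test_that("fixation-pair dispersion ratio is 1 for straight saccades", {
  # two fixations connected by one straight saccade rendered explicitly
  fs <- 360
  n <- 2 * fs
  x <- c(rep(0, 300), seq(0, 3, length.out = 20), rep(3, n - 320))
  rec <- gaze_recording((0:(n - 1)) / fs, x, rep(0, n), rep(3.5, n))
  ev <- make_event_sequence(
    c("fixation", "saccade", "fixation"),
    onset_s = c(0, 300 / fs, 320 / fs),
    offset_s = c(300 / fs, 320 / fs, 2))
  ev$events$center_x_cm <- c(0, NA, 3)
  ev$events$center_y_cm <- c(0, NA, 0)
  ev$events$onset_idx <- c(1L, 301L, 321L)
  ev$events$offset_idx <- c(300L, 320L, n)
  # a second identical pair so that >= 2 eligible pairs exist
  ev2 <- ev
  ev2$events <- rbind(ev$events, within(ev$events, {
    onset_s <- onset_s + 2; offset_s <- offset_s + 2
  }))
  ev2$events$onset_idx <- c(1L, 301L, 321L, 1L, 301L, 321L)
  ev2$events$offset_idx <- c(300L, 320L, 720L, 300L, 320L, 720L)
  fm <- fixation_metrics(ev2, rec, 4)
  expect_equal(fm$FF_disp_dist, 1, tolerance = 1e-9)
  expect_equal(fm$FF_disp, 3, tolerance = 1e-6)
  expect_equal(fm$FF_dist, 3, tolerance = 1e-6)
})

test_that("pupil metrics: summary statistics and phase regularity", {
  fs <- 360
  # constant 4 mm
  ps <- structure(list(time_s = (0:999) / fs, pupil_mm = rep(4, 1000),
                       blink_mask = rep(FALSE, 1000), fs = fs),
                  class = "pupil_series")
  pm <- pupil_metrics(ps)
  expect_equal(pm$PD, 4)
  expect_equal(pm$PDIR, 0)
  expect_equal(pm$PCV, 0)
  expect_true(is.na(pm$PH))

  # samples uniformly spanning [3, 5]: IQR = 1 (linear interpolation)
  ps2 <- ps; ps2$pupil_mm <- seq(3, 5, length.out = 1000)
  expect_equal(pupil_metrics(ps2)$PDIR, 1, tolerance = 1e-3)

  # pure sinusoid: constant phase increments, PH ~ 1
  t <- (0:3599) / fs
  ps3 <- structure(list(time_s = t,
                        pupil_mm = 4 + 0.3 * sin(2 * pi * 0.5 * t),
                        blink_mask = rep(FALSE, 3600), fs = fs),
                   class = "pupil_series")
  pm3 <- pupil_metrics(ps3)
  expect_gt(pm3$PH, 0.99)
  # blink-mask samples excluded from PD
  ps4 <- ps; ps4$pupil_mm[1:100] <- 9; ps4$blink_mask[1:100] <- TRUE
  expect_equal(pupil_metrics(ps4)$PD, 4)
  expect_error(pupil_metrics(ps, included_mask = rep(FALSE, 1000)),
               "included")
})

test_that("attention dynamics (coefficient K) from fixation-saccade pairs", {
  # durations and amplitudes constant: zero variance -> missing
  ev <- make_event_sequence(
    rep(c("fixation", "saccade"), 3),
    onset_s = c(0, 1, 1.1, 2.1, 2.2, 3.2),
    offset_s = c(1, 1.05, 2.1, 2.15, 3.2, 3.25),
    amplitude_deg = c(NA, 5, NA, 5, NA, 5))
  expect_true(is.na(attention_dynamics(ev)))

  # hand oracle on 3 pairs: durations d = (1, 2, 3), amplitudes
  # a = (6, 4, 2); z(d) = (-1, 0, 1), z(a) = (1, 0, -1); K = mean(z_d -
  # z_a) = 0
  ev2 <- make_event_sequence(
    rep(c("fixation", "saccade"), 3),
    onset_s = c(0, 1.0, 2, 4.0, 6, 9.0),
    offset_s = c(1, 1.05, 4, 4.05, 9, 9.05),
    amplitude_deg = c(NA, 6, NA, 4, NA, 2))
  expect_equal(attention_dynamics(ev2), 0, tolerance = 1e-9)

  # asymmetric case, hand-computed: d = (1, 2, 4), a = (2, 2, 5)
  # z(d) = (-0.87287..., -0.21822..., 1.09109...)
  # z(a) = (-0.57735, -0.57735, 1.15470); K = mean(z_d - z_a)
  d <- c(1, 2, 4); a <- c(2, 2, 5)
  k_oracle <- mean((d - mean(d)) / sd(d) - (a - mean(a)) / sd(a))
  ev3 <- make_event_sequence(
    rep(c("fixation", "saccade"), 3),
    onset_s = c(0, 1.0, 2, 4.0, 6, 10.0),
    offset_s = c(1, 1.05, 4, 4.05, 10, 10.05),
    amplitude_deg = c(NA, 2, NA, 2, NA, 5))
  expect_equal(attention_dynamics(ev3), k_oracle, tolerance = 1e-9)
})

test_that("segment features mask pauses and recover generator truth", {
  pr <- sample_participant_profile(seed = 31)
  syn <- synthesize_segment(pr, 0.3, duration_s = 60, seed = 31,
                            cycles_per_segment = 6L)
  rec <- syn$recording
  meta <- session_meta("P31", age = pr$age, sex = pr$sex, mode = "manual",
                       cycle_count = 6L, cycles_per_segment = 6L)
  sf <- compute_segment_features(rec, 1L, meta)
  expect_s3_class(sf, "segment_features")
  expect_equal(attr(sf, "duration_s"), 60)
  tf <- syn$truth$features
  # blink frequency within 3.5 sqrt(bf/T) of the generating rate
  expect_lt(abs(sf$BF - tf$BF), 3.5 * sqrt(tf$BF / 60) + 1e-9)
  expect_lt(abs(sf$SF - tf$SF) / tf$SF, 0.08)
  expect_equal(sf$age, pr$age)
  expect_equal(sf$sex, pr$sex)

  # content inside an excluded interval must not affect blink features:
  # appending a KSS pause + artificial blink content leaves BF unchanged
  n <- length(rec$time_s)
  fs <- 360
  extra_t <- max(rec$time_s) + (1:(5 * fs)) / fs
  extra_p <- rep(c(rep(0, 36), rep(3.5, 36)), length.out = 5 * fs)
  ann <- rbind(rec$annotations,
               data.frame(label = "kss_pause", start_s = 60, end_s = 65))
  rec2 <- gaze_recording(c(rec$time_s, extra_t),
                         c(rec$gaze_x_cm, rep(0, 5 * fs)),
                         c(rec$gaze_y_cm, rep(0, 5 * fs)),
                         c(rec$pupil_mm, extra_p),
                         geometry = rec$geometry, annotations = ann)
  sf2 <- compute_segment_features(rec2, 1L, meta)
  expect_equal(sf2$BF, sf$BF, tolerance = 1e-9)
  expect_equal(sf2$PERCLOS, sf$PERCLOS, tolerance = 1e-9)

  # a segment without annotated cycles errors
  expect_error(compute_segment_features(rec, 3L, meta), "segment 3")
})

test_that("features are invariant to uniform time translation", {
  pr <- sample_participant_profile(seed = 8)
  syn <- synthesize_segment(pr, 0.5, duration_s = 40, seed = 8,
                            cycles_per_segment = 4L)
  rec <- syn$recording
  meta <- session_meta("P8", age = pr$age, sex = pr$sex, mode = "manual",
                       cycle_count = 4L, cycles_per_segment = 4L)
  sf1 <- compute_segment_features(rec, 1L, meta)
  shift <- 123.4
  ann <- rec$annotations
  ann$start_s <- ann$start_s + shift; ann$end_s <- ann$end_s + shift
  rec_shift <- gaze_recording(rec$time_s + shift, rec$gaze_x_cm,
                              rec$gaze_y_cm, rec$pupil_mm,
                              geometry = rec$geometry, annotations = ann)
  sf2 <- compute_segment_features(rec_shift, 1L, meta)
  for (f in OCULOMETRIC_FEATURES) {
    expect_equal(sf2[[f]], sf1[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("rate features scale as 1/duration, ratios are invariant", {
  on <- seq(0.5, by = 2, length.out = 10)
  ev <- make_event_sequence(rep("blink", 10), on, on + 0.25)
  b1 <- blink_metrics(ev, 100, 0, 100)
  b2 <- blink_metrics(ev, 200, 0, 100)
  expect_equal(b1$BF / b2$BF, 2)
  expect_equal(b1$LBF / b2$LBF, 2)
  expect_equal(b1$LBR, b2$LBR)  # ratio invariant
  expect_equal(b1$BD, b2$BD)
})
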