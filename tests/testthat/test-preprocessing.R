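emg_ts <- function(values, fs = 200) {
  n <- if (is.null(dim(values))) length(values) else nrow(values)
  promet_ts(seq(0, by = 1 / fs, length.out = n), values, fs)
}

test_that("EMG filtering removes DC, notches 60 Hz and stays linear", {
  n <- 2000
  zero <- emg_ts(matrix(0, n, 2))
  expect_equal(max(abs(filter_emg(zero)$values)), 0)

  dc <- emg_ts(matrix(0.5, n, 1))
  expect_lt(mean(abs(filter_emg(dc)$values)), 0.005)

  t <- seq(0, by = 1 / 200, length.out = n)
  mains <- emg_ts(sin(2 * pi * 60 * t))
  out <- filter_emg(mains)$values
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(mains$values^2)), 0.10)

  set.seed(1)
  x <- emg_ts(rnorm(n))
  ax <- emg_ts(3.7 * x$values)
  expect_equal(filter_emg(ax)$values, 3.7 * filter_emg(x)$values,
               tolerance = 1e-9)

  slow <- promet_ts(seq(0, by = 1 / 100, length.out = 300),
                    rnorm(300), 100)
  expect_error(filter_emg(slow), class = "promet_nyquist_violation")
})

test_that("previous-neighbour upsampling repeats samples and inverts by decimation", {
  s <- promet_ts(c(0, 1 / 50), c(3, 7), 50)
  up <- upsample_hold(s, 200)
  expect_equal(as.vector(up$values), c(3, 3, 3, 3, 7, 7, 7, 7))
  expect_equal(up$fs, 200)

  one <- promet_ts(0, 5, 50)
  expect_equal(as.vector(upsample_hold(one, 200)$values), rep(5, 4))

  expect_error(upsample_hold(s, 130), class = "promet_bad_ratio")

  set.seed(2)
  s2 <- promet_ts(seq(0, by = 1 / 50, length.out = 40), rnorm(40), 50)
  up2 <- upsample_hold(s2, 200)
  expect_equal(as.vector(up2$values)[seq(1, 160, by = 4)],
               as.vector(s2$values))
})

test_that("linear upsampling interpolates and preserves ramps", {
  s <- promet_ts(c(0, 1 / 50), c(0, 10), 50)
  up <- upsample_linear(s, 100)
  expect_equal(as.vector(up$values), c(0, 5, 10))

  s3 <- promet_ts(c(0, 1, 2) / 50, c(0, 4, 8), 50)
  expect_equal(as.vector(upsample_linear(s3, 100)$values), c(0, 2, 4, 6, 8))

  ramp <- promet_ts(seq(0, 1, by = 1 / 50), seq(0, 100, length.out = 51), 50)
  up3 <- upsample_linear(ramp, 200)
  expect_equal(as.vector(up3$values), 100 * up3$t, tolerance = 1e-9)

  expect_error(upsample_linear(promet_ts(0, 1, 50), 100),
               class = "promet_too_few_samples")
})

test_that("window counts follow floor((N - L) / S) + 1, verified by brute force", {
  s <- promet_ts(seq(0, by = 1 / 200, length.out = 400), rnorm(400), 200)
  w <- window_signal(s)
  expect_equal(w$length, 32)
  expect_equal(w$stride, 8)
  expect_equal(length(w$windows), 47)

  s32 <- promet_ts(seq(0, by = 1 / 200, length.out = 32), rnorm(32), 200)
  expect_equal(length(window_signal(s32)$windows), 1)
  s31 <- promet_ts(seq(0, by = 1 / 200, length.out = 31), rnorm(31), 200)
  expect_error(window_signal(s31), class = "promet_too_few_samples")

  set.seed(3)
  for (i in 1:200) {
    N <- sample(40:500, 1)
    L_ms <- sample(20:200, 1)
    S_ms <- sample(5:L_ms, 1)
    cfg <- preprocess_config(window_ms = L_ms, window_offset_ms = S_ms)
    sN <- promet_ts(seq(0, by = 1 / 200, length.out = N), seq_len(N), 200)
    L <- round(L_ms * 200 / 1000); S <- round(S_ms * 200 / 1000)
    if (S < 1 || L < 1 || N < L) next
    # brute force: slide until the window no longer fits
    count <- 0L; st <- 1L
    while (st + L - 1L <= N) {
      count <- count + 1L
      st <- st + S
    }
    got <- window_signal(sN, cfg)
    expect_equal(length(got$windows), count)
    expect_equal(got$windows[[1]][, 1], as.numeric(seq_len(L)))
  }
})

test_that("moving average is centered, truncated at edges and range-bounded", {
  expect_equal(moving_average(rep(4, 10), 5), rep(4, 10))
  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(moving_average(imp, 3), c(0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0))
  expect_equal(moving_average(imp, 1), imp)
  expect_error(moving_average(1:5, 4), class = "promet_bad_window")
  expect_error(moving_average(1:5, 0), class = "promet_bad_window")

  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(sample(10:60, 1))
    w <- sample(c(3, 5, 7, 9), 1)
    sm <- moving_average(x, w)
    expect_true(all(sm <= max(x) + 1e-12 & sm >= min(x) - 1e-12))
  }
})

test_that("time derivative matches analytic slopes", {
  fs <- 120
  t <- seq(0, 1, by = 1 / fs)
  expect_equal(time_derivative(3.5 * t, fs), rep(3.5, length(t)),
               tolerance = 1e-9)
  expect_equal(time_derivative(rep(2, 50), fs), rep(0, 50))
  s <- sin(2 * pi * t)
  expect_equal(max(time_derivative(s, fs)), 2 * pi, tolerance = 0.01)
  expect_error(time_derivative(1:2, fs), class = "promet_too_few_samples")
})

test_that("motor calibration recovers polynomial maps", {
  x <- seq(-2, 3, length.out = 60)
  cal <- fit_motor_calibration(x, 2 * x + 1, degree = 3)
  expect_equal(apply_calibration(cal, x), 2 * x + 1, tolerance = 1e-9)

  y <- 0.5 - 1.2 * x + 0.3 * x^2 + 0.05 * x^3
  cal3 <- fit_motor_calibration(x, y, degree = 3)
  expect_equal(cal3$coefficients, c(0.5, -1.2, 0.3, 0.05), tolerance = 1e-9)

  expect_error(fit_motor_calibration(c(1, 2), c(1, 2), degree = 3),
               class = "promet_too_few_samples")
  expect_error(fit_motor_calibration(rep(1, 10), rnorm(10), degree = 2),
               class = "promet_degenerate_input")
})

test_that("marker-based aperture is a Euclidean distance with NaN passthrough", {
  thumb <- rbind(c(0, 0, 0), c(1, 1, 1), c(0, NaN, 0))
  index <- rbind(c(3, 4, 0), c(1, 1, 1), c(1, 1, 1))
  ap <- aperture_from_markers(thumb, index)
  expect_equal(ap[1], 5)
  expect_equal(ap[2], 0)
  expect_true(is.nan(ap[3]))
})

test_that("motor-stream recalculation pipeline matches kinematic truth", {
  g <- generate_trial("PASTA", seed = 21)
  tr <- g$trial
  up <- upsample_linear(tr$motor, 120)
  n <- min(length(up$t), length(tr$kinematics$t))
  ap_ref <- ts_channel(tr$kinematics, "aperture")[1:n]
  cal <- fit_motor_calibration(ts_channel(up, "hand_motor")[1:n], ap_ref, 3)
  pred <- apply_calibration(cal, ts_channel(up, "hand_motor")[1:n])
  # residual is dominated by 50 Hz linear-interpolation error on fast ramps
  expect_lt(max(abs(pred - ap_ref)), 2)
  expect_lt(stats::median(abs(pred - ap_ref)), 0.05)
  wr_ref <- ts_channel(tr$kinematics, "wrist_rot")[1:n]
  cal2 <- fit_motor_calibration(ts_channel(up, "wrist_motor")[1:n], wr_ref, 2)
  expect_lt(max(abs(apply_calibration(cal2, ts_channel(up, "wrist_motor")[1:n]) -
                      wr_ref)), 0.5)
})
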