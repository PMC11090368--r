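test_that("success rate is a guarded percentage", {
  expect_equal(success_rate(9, 10), 90)
  expect_equal(success_rate(0, 7), 0)
  expect_equal(success_rate(7, 7), 100)
  expect_error(success_rate(1, 0), class = "promet_bad_count")
  expect_error(success_rate(8, 7), class = "promet_bad_count")
})

test_that("trial duration spans first phase start to last phase end", {
  mk_phase <- function(t0, d) {
    starts <- t0 + cumsum(c(0, d[-5]))
    data.frame(label = c("Reach", "Grasp", "Transport", "Release", "Home"),
               start_s = starts, end_s = starts + d)
  }
  mk_mv <- function(t0, d) {
    ph <- mk_phase(t0, d)
    list(start_s = ph$start_s[1], end_s = ph$end_s[5], phases = ph,
         segments = promet:::derive_segments(ph))
  }
  # trial spans 2.00 to 27.28 s
  mv <- list(mk_mv(2, c(1, 2, 3, 1.5, 0.9)),
             mk_mv(11, c(1, 2, 3, 1.5, 0.9)),
             mk_mv(19.5, c(1.6, 2, 3, 0.7, 0.48)))
  seg <- promet:::new_segmentation(mv)
  expect_equal(trial_duration(seg), 25.28)
  # contiguous phases: trial duration equals the sum of all phase durations
  # plus the between-movement gaps (zero gaps here would make them equal)
  expect_equal(phase_duration(seg, 1, "Grasp"), 2)
  expect_error(phase_duration(seg, 1, "Home"), class = "promet_bad_level")
})

test_that("relative phase durations are percent of the Reach..Release span", {
  d <- c(1, 2, 3, 4, 0.5)
  starts <- cumsum(c(0, d[-5]))
  ph <- data.frame(label = c("Reach", "Grasp", "Transport", "Release", "Home"),
                   start_s = starts, end_s = starts + d)
  mv <- list(start_s = 0, end_s = ph$end_s[5], phases = ph,
             segments = promet:::derive_segments(ph))
  shift <- function(m, by) {
    m$phases$start_s <- m$phases$start_s + by
    m$phases$end_s <- m$phases$end_s + by
    m$start_s <- m$start_s + by; m$end_s <- m$end_s + by
    m$segments <- promet:::derive_segments(m$phases)
    m
  }
  seg <- promet:::new_segmentation(list(mv, shift(mv, 11), shift(mv, 22)))
  rel <- vapply(c("Reach", "Grasp", "Transport", "Release"),
                function(p) relative_phase_duration(seg, 1, p), numeric(1))
  expect_equal(unname(rel), c(10, 20, 30, 40))
  expect_equal(sum(rel), 100, tolerance = 1e-6)

  # equal phases split evenly
  d2 <- rep(1.5, 5)
  starts2 <- cumsum(c(0, d2[-5]))
  ph2 <- data.frame(label = ph$label, start_s = starts2, end_s = starts2 + d2)
  mv2 <- list(start_s = 0, end_s = ph2$end_s[5], phases = ph2,
              segments = promet:::derive_segments(ph2))
  seg2 <- promet:::new_segmentation(list(mv2, shift(mv2, 10), shift(mv2, 20)))
  expect_equal(relative_phase_duration(seg2, 2, "Grasp"), 25)
})

test_that("peak hand velocity matches the minimum-jerk closed form", {
  fs <- 120
  set.seed(13)
  for (i in 1:50) {
    D <- runif(1, 150, 600)
    T <- runif(1, 0.5, 1.5)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    mj <- min_jerk(c(0, 0, 0), D * dir, T, fs)
    # pad with rest so the zero-phase low-pass sees a settled signal
    pad <- matrix(rep(mj$xyz[nrow(mj$xyz), ], 30), ncol = 3, byrow = TRUE)
    pad0 <- matrix(rep(mj$xyz[1, ], 30), ncol = 3, byrow = TRUE)
    xyz <- rbind(pad0, mj$xyz, pad)
    expect_equal(peak_hand_velocity(xyz, fs), 15 * D / (8 * T),
                 tolerance = 0.02)
  }
  # straight line at constant speed
  t <- seq(0, 1, by = 1 / fs)
  line <- cbind(300 * t, 0 * t, 0 * t)
  expect_equal(peak_hand_velocity(line, fs), 300, tolerance = 0.01 * 300)
  expect_lt(peak_hand_velocity(matrix(5, 50, 3), fs), 0.01)
})

test_that("hand distance travelled sums successive displacements", {
  path <- cbind(seq(0, 500, length.out = 100), 0, 0)
  expect_equal(hand_distance_travelled(path), 500, tolerance = 0.5)
  there <- cbind(seq(0, 200, length.out = 50), 0, 0)
  back <- there[seq(nrow(there) - 1, 1), ]
  expect_equal(hand_distance_travelled(rbind(there, back)), 400,
               tolerance = 1e-9)
  expect_equal(hand_distance_travelled(matrix(1, 10, 3)), 0)
  expect_error(hand_distance_travelled(matrix(1, 1, 3)),
               class = "promet_too_few_samples")

  # triangle inequality on random walks
  set.seed(14)
  for (i in 1:100) {
    walk <- apply(matrix(rnorm(3 * 40), ncol = 3), 2, cumsum)
    expect_gte(hand_distance_travelled(walk) + 1e-12,
               sqrt(sum((walk[40, ] - walk[1, ])^2)))
  }
})

test_that("trajectory variability has the two-trial closed form and invariances", {
  t <- seq(0, 1, length.out = 90)
  base <- cbind(sin(t * 2), cos(t), t * 100)
  expect_equal(hand_trajectory_variability(list(base, base)), 0)

  offset <- base
  offset[, 1] <- offset[, 1] + 3
  v <- hand_trajectory_variability(list(base, offset))
  expect_equal(v, 3 / (3 * sqrt(2)), tolerance = 1e-9)

  # common rigid translation leaves variability unchanged
  sh <- function(m) sweep(m, 2, c(12, -5, 40), `+`)
  expect_equal(hand_trajectory_variability(list(sh(base), sh(offset))), v,
               tolerance = 1e-12)

  # uniform re-timing of one trial (same path, more samples) is absorbed
  dense <- cbind(sin(seq(0, 1, length.out = 300) * 2),
                 cos(seq(0, 1, length.out = 300)),
                 seq(0, 1, length.out = 300) * 100)
  dense[, 1] <- dense[, 1] + 3
  v2 <- hand_trajectory_variability(list(base, dense))
  expect_equal(v2, v, tolerance = 1e-3)

  expect_error(hand_trajectory_variability(list(base)),
               class = "promet_too_few_trials")
})
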