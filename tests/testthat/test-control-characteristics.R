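test_that("total excursion sums absolute successive differences", {
  expect_equal(total_excursion(c(50, 52, 49, 49)), 5)
  expect_equal(total_excursion(rep(7, 20)), 0)
  ramp <- seq(12, 60, length.out = 33)
  expect_equal(total_excursion(ramp), 48, tolerance = 1e-12)
  expect_error(total_excursion(1), class = "promet_too_few_samples")

  set.seed(15)
  for (i in 1:100) {
    x <- rnorm(sample(5:50, 1))
    expect_gte(total_excursion(x) + 1e-12, abs(x[length(x)] - x[1]))
  }
})

test_that("adjustment counting matches the stated transition rule", {
  # the rule on an explicit sign sequence: 0,0,+,+,-,-,0,0,- has 3 counted
  s <- c(0, 0, 1, 1, -1, -1, 0, 0, -1)
  tr <- promet:::count_sign_transitions(s)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$from, c(0, 1, 0))
  expect_equal(tr$to, c(1, -1, -1))

  fs <- 120
  t <- seq(0, 1.5, by = 1 / fs)
  expect_equal(count_adjustments(rep(30, 80), fs)$count, 0)

  # a single monotone opening is one onset transition
  open <- c(rep(20, 40), 20 + 40 * promet:::mj_s(seq(0, 1, length.out = 60)),
            rep(60, 40))
  expect_equal(count_adjustments(open, fs)$count, 1)
})

test_that("adjustment counting equals the brute-force enumerator on random traces", {
  set.seed(16)
  fs <- 120
  for (i in 1:300) {
    n <- sample(30:200, 1)
    # mixture of smooth ramps, flats and noise so all sign states occur
    x <- cumsum(rnorm(n, 0, 2)) * sample(c(0.1, 1, 5), 1)
    if (runif(1) < 0.5) x[seq_len(sample.int(n %/% 2, 1))] <- x[1]
    got <- count_adjustments(x, fs)$count
    want <- oracle_count_adjustments(x, fs)
    expect_identical(got, want)
  }
})

test_that("injected adjustment reversals are recovered exactly", {
  for (seed in 1:4) {
    for (K in 0:6) {
      mv <- lapply(1:3, function(m) {
        movement_params(extra_ap_adj = c(Transport = K),
                        extra_wr_adj = c(Grasp = K))
      })
      g <- generate_trial("RCRT_DOWN", mv, seed = 100 * seed + K)
      seg <- truth_segmentation(g$truth)
      t <- g$trial$kinematics$t
      ap <- ts_channel(g$trial$kinematics, "aperture")
      wr <- ts_channel(g$trial$kinematics, "wrist_rot")
      for (m in 1:3) {
        w <- promet:::seg_phase(seg, m, "Transport")
        sel <- t >= w$start_s - 1e-9 & t <= w$end_s + 1e-9
        expect_identical(count_adjustments(ap[sel])$count, K)
        w <- promet:::seg_phase(seg, m, "Grasp")
        sel <- t >= w$start_s - 1e-9 & t <= w$end_s + 1e-9
        expect_identical(count_adjustments(wr[sel])$count, K)
      }
    }
  }
})

test_that("grip aperture plateau obeys its threshold semantics", {
  fs <- 120
  # open 0.5 s, hold 0.8 s at max, close 0.5 s
  u <- seq(0, 1, length.out = round(0.5 * fs))
  ap <- c(rep(20, 12), 20 + 60 * promet:::mj_s(u), rep(80, round(0.8 * fs)),
          80 - 50 * promet:::mj_s(u), rep(30, 12))
  expect_equal(grip_aperture_plateau(ap, fs), 0.8, tolerance = 0.1)

  # strictly monotone 1 s ramp: only near-peak deceleration samples qualify
  ramp <- 20 + 60 * promet:::mj_s(seq(0, 1, length.out = fs))
  expect_lt(grip_aperture_plateau(ramp, fs), 0.1)

  # constant trace: full segment duration (inclusive zero-velocity rule)
  expect_equal(grip_aperture_plateau(rep(55, 3 * fs), fs), 3)

  # never longer than the segment, and invariant to amplitude scaling
  set.seed(17)
  for (i in 1:30) {
    n <- sample(60:240, 1)
    x <- abs(cumsum(rnorm(n))) + 1
    p <- grip_aperture_plateau(x, fs)
    expect_lte(p, n / fs + 1e-12)
    expect_equal(grip_aperture_plateau(3.7 * x, fs), p, tolerance = 1e-12)
  }
})

test_that("plateau of generated trials matches the ledger", {
  for (ext in c(0, 0.3)) {
    mv <- replicate(3, movement_params(plateau_extension_s = ext),
                    simplify = FALSE)
    g <- generate_trial("PASTA", mv, seed = 18)
    seg <- segment_trial(g$trial)
    t <- g$trial$kinematics$t
    ap <- ts_channel(g$trial$kinematics, "aperture")
    for (m in 1:3) {
      w <- promet:::seg_segment(seg, m, "Reach-Grasp")
      sel <- t >= w$start_s - 1e-9 & t <= w$end_s + 1e-9
      expect_equal(grip_aperture_plateau(ap[sel]),
                   g$truth$movements[[m]]$plateau_s, tolerance = 0.1)
    }
  }
})

test_that("simultaneity is a bounded percentage with correct extremes", {
  fs <- 120
  t <- seq(0, 2, by = 1 / fs)
  both <- 30 * t
  expect_equal(simultaneous_wrist_shoulder(both, 10 * t, t, c(0.5, 1.5), fs),
               100, tolerance = 2)
  expect_equal(simultaneous_wrist_shoulder(both, rep(5, length(t)), t,
                                           c(0.5, 1.5), fs), 0)
  expect_error(simultaneous_wrist_shoulder(both, both, t, c(1, 1), fs),
               class = "promet_bad_window")

  # scripted overlap recovered from the generator ledger
  for (f in c(0.3, 0.5, 0.8)) {
    mv <- replicate(3, movement_params(sim_overlap_frac = f), simplify = FALSE)
    g <- generate_trial("RCRT_UP", mv, seed = 19)
    seg <- segment_trial(g$trial)
    t2 <- g$trial$kinematics$t
    wr <- ts_channel(g$trial$kinematics, "wrist_rot")
    sh <- ts_channel(g$trial$kinematics, "shoulder_fe")
    for (m in 1:3) {
      msel <- t2 >= seg$movements[[m]]$start_s & t2 <= seg$movements[[m]]$end_s
      for (ph in c("Reach", "Transport")) {
        got <- simultaneous_wrist_shoulder(wr[msel], sh[msel], t2[msel],
                                           unlist(promet:::seg_phase(seg, m, ph)))
        expect_gte(got, 0); expect_lte(got, 100)
        expect_equal(got, g$truth$movements[[m]]$simultaneity[[ph]],
                     tolerance = 2)
      }
    }
  }
})

test_that("total muscle activity normalizes against rest and is linear", {
  fs <- 200
  t <- seq(0, 4, by = 1 / fs)
  set.seed(20)
  mk_emg <- function(burst_amp) {
    vals <- sapply(1:8, function(ch) {
      x <- rnorm(length(t), 0, 0.02)
      inb <- t >= 1.5 & t <= 2.5
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = sum(inb)))
      x[inb] <- x[inb] + burst_amp * env * rnorm(sum(inb))
      x
    })
    colnames(vals) <- paste0("emg_", 1:8)
    promet_ts(t, vals, fs)
  }
  rest_like <- mk_emg(0)
  rest <- rest_reference_from_emg(rest_like)
  act <- total_muscle_activity(rest_like, rest, c(0.5, 3.5))
  unsub <- total_muscle_activity(rest_like, rest_reference(rep(0, 8)),
                                 c(0.5, 3.5))
  expect_lt(abs(act), 0.02 * abs(unsub))

  zero <- promet_ts(t, matrix(0, length(t), 8,
                              dimnames = list(NULL, paste0("emg_", 1:8))), fs)
  expect_equal(total_muscle_activity(zero, rest_reference(rep(0, 8)),
                                     c(0.5, 3.5)), 0)

  # doubling a pure burst doubles the summed envelope (zero rest means)
  mk_burst <- function(amp, seed) {
    set.seed(seed)
    vals <- sapply(1:8, function(ch) {
      x <- numeric(length(t))
      inb <- t >= 1.5 & t <= 2.5
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = sum(inb)))
      x[inb] <- amp * env * rnorm(sum(inb))
      x
    })
    colnames(vals) <- paste0("emg_", 1:8)
    promet_ts(t, vals, fs)
  }
  zr <- rest_reference(rep(0, 8))
  a1 <- total_muscle_activity(mk_burst(0.2, 33), zr, c(1.4, 2.6))
  a2 <- total_muscle_activity(mk_burst(0.4, 33), zr, c(1.4, 2.6))
  expect_equal(a2 / a1, 2, tolerance = 0.01)
  expect_error(total_muscle_activity(e1, NULL, c(1, 2)),
               class = "promet_bad_rest_reference")
})
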