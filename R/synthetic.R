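#' Minimum-jerk point-to-point trajectory
#'
#' Quintic minimum-jerk profile with zero boundary velocity and
#' acceleration; peak speed is `15 * |end - start| / (8 * T)` at mid-course.
#' Used as the movement kernel of the synthetic trial generator.
#'
#' @param start,end 3D positions (mm).
#' @param T Movement duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return List with `t` (seconds from 0) and `xyz` (n x 3 positions).
#' @export
min_jerk <- function(start, end, T, fs = 120) {
  if (T <= 0) stop_promet("bad_config", "duration must be positive")
  t <- seq(0, T, by = 1 / fs)
  s <- mj_s(t / T)
  list(t = t, xyz = outer(s, as.numeric(end) - as.numeric(start)) +
         matrix(as.numeric(start), length(t), 3, byrow = TRUE))
}

mj_s <- function(u) u^3 * (10 - 15 * u + 6 * u^2)
mj_v <- function(u) 30 * u^2 * (1 - u)^2  # d s / d u

# Piecewise min-jerk scalar signal: pieces df(t0, t1, v0, v1); constant
# between pieces (value = last completed target, v0 of first piece before).
eval_pieces <- function(pieces, t) {
  out <- rep(pieces$v0[1], length(t))
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    out[t >= p$t1] <- p$v1
    inp <- t >= p$t0 & t < p$t1
    out[inp] <- p$v0 + (p$v1 - p$v0) * mj_s((t[inp] - p$t0) / (p$t1 - p$t0))
  }
  out
}

eval_pieces_deriv <- function(pieces, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    inp <- t >= p$t0 & t < p$t1
    Td <- p$t1 - p$t0
    out[inp] <- (p$v1 - p$v0) * mj_v((t[inp] - p$t0) / Td) / Td
  }
  out
}

piece <- function(t0, t1, v0, v1) data.frame(t0 = t0, t1 = t1, v0 = v0, v1 = v1)

# Threshold crossing times of one min-jerk piece: speed = |amp| * mj_v(u) / T.
# Returns c(rise, fall) in absolute seconds, NA when the piece never crosses.
piece_crossings <- function(t0, t1, amp, thr) {
  T <- t1 - t0
  pk <- abs(amp) * 1.875 / T
  if (pk <= thr) return(c(NA_real_, NA_real_))
  q <- sqrt(thr * T / (30 * abs(amp)))
  r <- sqrt(1 - 4 * q)
  c(t0 + T * (1 - r) / 2, t0 + T * (1 + r) / 2)
}

#' Task geometry for the built-in functional tasks
#'
#' Approximate layouts (mm, lab frame) of the pasta-box relocation task
#' (one box moved side table, low shelf, high shelf and back) and
#' the clothespin relocation task (three pins between a horizontal and a
#' vertical bar at increasing heights). Only the relative structure matters
#' for metric testing; coordinates are configurable constants.
#'
#' @param task_id One of `"PASTA"`, `"RCRT_UP"`, `"RCRT_DOWN"`.
#' @return List with `home`, per-movement `sources` and `dests` (3D mm),
#'   `object_of_movement` (which object moves in each movement) and
#'   `n_objects`.
#' @export
task_geometry <- function(task_id) {
  task_id <- match.arg(task_id, c("PASTA", "RCRT_UP", "RCRT_DOWN"))
  if (task_id == "PASTA") {
    L <- list(c(250, -350, 750), c(420, 0, 950), c(-150, 80, 1250))
    list(home = c(0, 0, 800),
         sources = list(L[[1]], L[[2]], L[[3]]),
         dests = list(L[[2]], L[[3]], L[[1]]),
         object_of_movement = c(1L, 1L, 1L), n_objects = 1L)
  } else {
    horiz <- lapply(1:3, function(k) c(350, -120 + 60 * k, 900))
    vert <- lapply(1:3, function(k) c(380, 80, 850 + 150 * k))
    if (task_id == "RCRT_UP") {
      list(home = c(0, 0, 800), sources = horiz, dests = vert,
           object_of_movement = 1:3, n_objects = 3L)
    } else {
      list(home = c(0, 0, 800), sources = vert, dests = horiz,
           object_of_movement = 1:3, n_objects = 3L)
    }
  }
}

#' Per-movement generation parameters
#'
#' Scripted phase durations plus the controllable degradation knobs that
#' emulate the limb position effect: extra aperture/wrist adjustment
#' reversals per phase, a longer grip-aperture plateau, larger hand
#' trajectory noise, scaled wrist excursion amplitude, reduced
#' wrist-shoulder simultaneity overlap, and scaled EMG burst effort.
#'
#' @param reach_s,grasp_s,transport_s,release_s,home_s Phase durations (s).
#' @param extra_ap_adj,extra_wr_adj Named counts of injected adjustment
#'   reversals per phase (names among Reach/Grasp/Transport/Release).
#' @param plateau_extension_s Extra plateau hold before closing (s).
#' @param trajectory_noise_mm RMS of the smooth hand-path noise (mm).
#' @param wrist_excursion_scale Multiplier on injected wrist wiggle size.
#' @param sim_overlap_frac Fraction of Reach/Transport during which the
#'   wrist rotates (controls the simultaneity metric).
#' @param emg_effort_scale Multiplier on EMG burst amplitude.
#' @return List of class `promet_moveparams`.
#' @export
movement_params <- function(reach_s = 0.8, grasp_s = 0.5, transport_s = 1.2,
                            release_s = 0.4, home_s = 0.6,
                            extra_ap_adj = c(), extra_wr_adj = c(),
                            plateau_extension_s = 0, trajectory_noise_mm = 0,
                            wrist_excursion_scale = 1, sim_overlap_frac = 0.6,
                            emg_effort_scale = 1) {
  ap <- wr <- c(Reach = 0, Grasp = 0, Transport = 0, Release = 0)
  ap[names(extra_ap_adj)] <- extra_ap_adj
  wr[names(extra_wr_adj)] <- extra_wr_adj
  grasp_s <- grasp_s + plateau_extension_s + 0.18 * ap[["Grasp"]] +
    0.18 * wr[["Grasp"]]
  structure(list(reach_s = reach_s, grasp_s = grasp_s,
                 transport_s = transport_s, release_s = release_s,
                 home_s = home_s, extra_ap_adj = ap, extra_wr_adj = wr,
                 plateau_extension_s = plateau_extension_s,
                 trajectory_noise_mm = trajectory_noise_mm,
                 wrist_excursion_scale = wrist_excursion_scale,
                 sim_overlap_frac = sim_overlap_frac,
                 emg_effort_scale = emg_effort_scale),
            class = "promet_moveparams")
}

# Alternating-sign wiggle train: K min-jerk ramps with quiet gaps, starting
# upward, appended to `pieces`. Returns updated pieces and final value.
add_wiggles <- function(pieces, from_s, to_s, K, amp, cur) {
  if (K < 1) return(list(pieces = pieces, cur = cur))
  dw <- 0.12; gap <- 0.05
  need <- K * dw + (K - 1) * gap
  avail <- to_s - from_s
  if (need > avail) {
    dw <- max(0.05, (avail - (K - 1) * gap) / K)
    need <- K * dw + (K - 1) * gap
  }
  t <- from_s + (avail - need) / 2
  sgn <- 1
  for (k in seq_len(K)) {
    pieces <- rbind(pieces, piece(t, t + dw, cur, cur + sgn * amp))
    cur <- cur + sgn * amp
    t <- t + dw + gap
    sgn <- -sgn
  }
  list(pieces = pieces, cur = cur)
}

shoulder_angle <- function(z) (z - 800) * 0.08  # deg per mm of target height

#' Generate one synthetic functional-task trial with ground truth
#'
#' Builds a scripted trial — three Reach/Grasp/Transport/Release/Home
#' movements of the given task geometry, min-jerk hand and object paths,
#' scripted aperture open/plateau/close ramps, wrist/shoulder ramps with a
#' controlled simultaneity overlap, injected adjustment reversals, and
#' synthetic 8-channel EMG (rest noise plus effort bursts) — and returns the
#' sampled [trial_recording()] together with a ground-truth ledger.
#'
#' The ledger stores, per movement: the scripted phase boundaries; the
#' threshold-consistent boundaries a speed-threshold detector can recover
#' (closed-form crossing times of the analytic speed profiles, since the
#' sub-threshold tails of a minimum-jerk ramp are invisible to any
#' threshold rule); the reach/transport amplitude and duration; injected
#' adjustment counts, analytic excursions, plateau duration and
#' simultaneity percentages per phase.
#'
#' @param task_id Task label; selects [task_geometry()].
#' @param movements List of 3 [movement_params()].
#' @param seed Integer seed; identical inputs give identical output.
#' @param participant_id,controller_id,trial_index,error_free Trial
#'   identifiers.
#' @param geometry Optional geometry override.
#' @param seg_cfg [segmentation_config()] whose thresholds define the
#'   ledger's detectable boundaries.
#' @param with_motor Include a 50 Hz motor stream.
#' @return List with `trial` (a `promet_trial`) and `truth` (the ledger).
#' @export
generate_trial <- function(task_id = "PASTA",
                           movements = replicate(3, movement_params(),
                                                 simplify = FALSE),
                           seed = 1L, participant_id = "P1",
                           controller_id = "A", trial_index = 1L,
                           error_free = TRUE, geometry = NULL,
                           seg_cfg = segmentation_config(),
                           with_motor = TRUE) {
  stopifnot(length(movements) == 3L)
  geo <- geometry %||% task_geometry(task_id)
  if (any(vapply(seq_len(3L), function(k) {
    sqrt(sum((geo$sources[[k]] - geo$dests[[k]])^2)) < 1e-6
  }, logical(1)))) {
    stop_promet("bad_config", "coincident source/destination locations")
  }
  set.seed(as.integer(seed))
  fs_kin <- 120; fs_emg <- 200; fs_motor <- 50
  lead <- 0.5; tail <- 0.5
  a0 <- 20; amax <- 80; agrip <- 30; arel <- 60
  wiggle_ap <- 6
  wrist_amp <- if (task_id == "PASTA") 15 else 80

  hand_pieces <- NULL     # df(t0, t1, x0..z0, x1..z1)
  ap_pieces <- piece(-1, -0.5, a0, a0)
  wr_pieces <- piece(-1, -0.5, 0, 0)
  sh_pieces <- piece(-1, -0.5, shoulder_angle(geo$home[3]), shoulder_angle(geo$home[3]))
  obj_pieces <- vector("list", geo$n_objects)  # transport hand piece per object
  sched <- vector("list", 3L)
  cur_ap <- a0; cur_wr <- 0; cur_sh <- shoulder_angle(geo$home[3])
  t0 <- lead

  for (m in seq_len(3L)) {
    p <- movements[[m]]
    src <- geo$sources[[m]]; dst <- geo$dests[[m]]
    b <- cumsum(c(t0, p$reach_s, p$grasp_s, p$transport_s, p$release_s, p$home_s))
    names(b) <- c("reach0", "grasp0", "transport0", "release0", "home0", "end")
    # hand: reach, transport, home-return (70% of Home, then settle)
    hand_pieces <- rbind(hand_pieces,
      data.frame(t0 = b[["reach0"]], t1 = b[["grasp0"]], seg = "reach", m = m,
                 x0 = geo$home[1], y0 = geo$home[2], z0 = geo$home[3],
                 x1 = src[1], y1 = src[2], z1 = src[3]),
      data.frame(t0 = b[["transport0"]], t1 = b[["release0"]], seg = "transport",
                 m = m, x0 = src[1], y0 = src[2], z0 = src[3],
                 x1 = dst[1], y1 = dst[2], z1 = dst[3]),
      data.frame(t0 = b[["home0"]], t1 = b[["home0"]] + 0.7 * p$home_s,
                 seg = "home", m = m,
                 x0 = dst[1], y0 = dst[2], z0 = dst[3],
                 x1 = geo$home[1], y1 = geo$home[2], z1 = geo$home[3]))
    # aperture: open in Reach, plateau, close in Grasp, open in Release
    open0 <- b[["reach0"]] + 0.20 * p$reach_s
    open1 <- open0 + 0.45 * p$reach_s
    close0 <- b[["grasp0"]] + 0.1 * (p$grasp_s - p$plateau_extension_s) +
      p$plateau_extension_s
    close1 <- close0 + 0.2 * p$grasp_s
    ap_pieces <- rbind(ap_pieces, piece(open0, open1, cur_ap, amax),
                       piece(close0, close1, amax, agrip))
    cur_ap <- agrip
    wg <- add_wiggles(ap_pieces, close1 + 0.05, b[["transport0"]] - 0.05,
                      p$extra_ap_adj[["Grasp"]], wiggle_ap, cur_ap)
    ap_pieces <- wg$pieces; cur_ap <- wg$cur
    # transport wiggles stay clear of the detectable phase boundaries (the
    # object-speed crossings sit ~6% of the ramp inside the scripted bounds)
    wg <- add_wiggles(ap_pieces, b[["transport0"]] + 0.12 * p$transport_s,
                      b[["release0"]] - 0.12 * p$transport_s,
                      p$extra_ap_adj[["Transport"]], wiggle_ap, cur_ap)
    ap_pieces <- wg$pieces; cur_ap <- wg$cur
    rel0 <- b[["release0"]] + 0.1 * p$release_s
    rel1 <- rel0 + 0.5 * p$release_s
    ap_pieces <- rbind(ap_pieces, piece(rel0, rel1, cur_ap, arel))
    cur_ap <- arel
    wg <- add_wiggles(ap_pieces, rel1 + 0.03, b[["home0"]] - 0.08,
                      p$extra_ap_adj[["Release"]], wiggle_ap, cur_ap)
    ap_pieces <- wg$pieces; cur_ap <- wg$cur
    hm0 <- b[["home0"]] + 0.1 * p$home_s
    ap_pieces <- rbind(ap_pieces, piece(hm0, hm0 + 0.4 * p$home_s, cur_ap, a0))
    cur_ap <- a0
    # wrist: overlap-controlled ramps in Reach and Transport, wiggles, unwind
    f <- p$sim_overlap_frac
    wr_r0 <- b[["reach0"]] + 0.5 * (1 - f) * p$reach_s
    wr_pieces <- rbind(wr_pieces,
                       piece(wr_r0, wr_r0 + f * p$reach_s, cur_wr, cur_wr + wrist_amp))
    cur_wr <- cur_wr + wrist_amp
    wg <- add_wiggles(wr_pieces, b[["grasp0"]] + 0.05, b[["transport0"]] - 0.03,
                      p$extra_wr_adj[["Grasp"]], 8 * p$wrist_excursion_scale, cur_wr)
    wr_pieces <- wg$pieces; cur_wr <- wg$cur
    wr_t0 <- b[["transport0"]] + 0.5 * (1 - f) * p$transport_s
    wr_pieces <- rbind(wr_pieces,
                       piece(wr_t0, wr_t0 + f * p$transport_s, cur_wr, cur_wr - wrist_amp))
    cur_wr <- cur_wr - wrist_amp
    wg <- add_wiggles(wr_pieces, b[["release0"]] + 0.03, b[["home0"]] - 0.02,
                      p$extra_wr_adj[["Release"]], 8 * p$wrist_excursion_scale, cur_wr)
    wr_pieces <- wg$pieces; cur_wr <- wg$cur
    if (abs(cur_wr) > 1e-9) {
      hm0 <- b[["home0"]] + 0.05 * p$home_s
      wr_pieces <- rbind(wr_pieces, piece(hm0, hm0 + 0.5 * p$home_s, cur_wr, 0))
      cur_wr <- 0
    }
    # shoulder: tracks target height through Reach, Transport, Home
    sh_pieces <- rbind(sh_pieces,
      piece(b[["reach0"]], b[["grasp0"]], cur_sh, shoulder_angle(src[3])),
      piece(b[["transport0"]], b[["release0"]], shoulder_angle(src[3]),
            shoulder_angle(dst[3])),
      # unhurried return spanning Release + Home so its peak angular speed
      # does not dwarf the reach ramp (the simultaneity thresholds are
      # fractions of the movement maximum)
      piece(b[["release0"]], b[["home0"]] + 0.7 * p$home_s,
            shoulder_angle(dst[3]), shoulder_angle(geo$home[3])))
    cur_sh <- shoulder_angle(geo$home[3])
    obj <- geo$object_of_movement[m]
    obj_pieces[[obj]] <- rbind(obj_pieces[[obj]],
      data.frame(t0 = b[["transport0"]], t1 = b[["release0"]], m = m,
                 x0 = src[1], y0 = src[2], z0 = src[3],
                 x1 = dst[1], y1 = dst[2], z1 = dst[3]))
    sched[[m]] <- list(bounds = b, params = p, src = src, dst = dst)
    t0 <- b[["end"]]
  }
  total <- t0 + tail

  # ---- sample the script ---------------------------------------------------
  tk <- seq(0, total, by = 1 / fs_kin)
  hand <- sample_xyz_pieces(hand_pieces, tk, geo$home)
  # path noise is one smooth per-trial curve at the largest requested RMS;
  # movement-to-movement contrast comes from the other degradation knobs
  sig <- max(vapply(movements, `[[`, numeric(1), "trajectory_noise_mm"))
  if (sig > 0) {
    for (ax in 1:3) hand[, ax] <- hand[, ax] + smooth_noise(tk, sig)
  }
  aperture <- eval_pieces(ap_pieces, tk)
  wrist <- eval_pieces(wr_pieces, tk)
  shoulder <- eval_pieces(sh_pieces, tk)
  objs <- lapply(seq_len(geo$n_objects), function(o) {
    start <- if (o %in% geo$object_of_movement) {
      m1 <- which(geo$object_of_movement == o)[1]
      geo$sources[[m1]]
    } else c(300, 200, 900)
    sample_xyz_pieces(obj_pieces[[o]], tk, start)
  })
  obj_mat <- do.call(cbind, lapply(seq_along(objs), function(o) {
    m <- objs[[o]]; colnames(m) <- paste0("obj", o, c("_x", "_y", "_z")); m
  }))
  kin <- promet_ts(tk, cbind(hand_x = hand[, 1], hand_y = hand[, 2],
                             hand_z = hand[, 3], aperture = aperture,
                             wrist_rot = wrist, shoulder_fe = shoulder),
                   fs_kin)
  objects <- promet_ts(tk, obj_mat, fs_kin)
  emg <- synth_emg(total, fs_emg, sched, movements)
  motor <- NULL
  if (with_motor) {
    tm <- seq(0, total, by = 1 / fs_motor)
    apm <- eval_pieces(ap_pieces, tm); wrm <- eval_pieces(wr_pieces, tm)
    motor <- promet_ts(tm, cbind(hand_motor = 2 * sqrt(apm + 5),
                                 wrist_motor = 10 + 2 * wrm), fs_motor)
  }
  trial <- trial_recording(participant_id, controller_id, task_id, trial_index,
                           error_free, kin, objects, emg, motor)
  truth <- trial_truth(sched, hand_pieces, ap_pieces, wr_pieces, sh_pieces,
                       seg_cfg, task_id)
  list(trial = trial, truth = truth)
}

sample_xyz_pieces <- function(pieces, t, init) {
  if (is.null(pieces)) {
    return(matrix(init, length(t), 3, byrow = TRUE))
  }
  vapply(1:3, function(ax) {
    p <- data.frame(t0 = pieces$t0, t1 = pieces$t1,
                    v0 = pieces[[c("x0", "y0", "z0")[ax]]],
                    v1 = pieces[[c("x1", "y1", "z1")[ax]]])
    eval_pieces(p, t)
  }, numeric(length(t)))
}

# Smooth low-frequency path noise with RMS sigma (sum of 3 random sinusoids).
smooth_noise <- function(t, sigma) {
  a <- stats::rnorm(3); f <- stats::runif(3, 0.2, 0.8)
  ph <- stats::runif(3, 0, 2 * pi)
  curve <- rowSums(vapply(1:3, function(j) a[j] * sin(2 * pi * f[j] * t + ph[j]),
                          numeric(length(t))))
  s <- stats::sd(curve)
  if (s < 1e-12) return(numeric(length(t)))
  curve * sigma / s
}

synth_emg <- function(total, fs, sched, movements) {
  te <- seq(0, total, by = 1 / fs)
  w <- seq(0.5, 1.2, length.out = 8)
  base_sd <- 0.02
  vals <- vapply(1:8, function(ch) {
    x <- stats::rnorm(length(te), 0, base_sd)
    for (m in 1:3) {
      b <- sched[[m]]$bounds
      eff <- movements[[m]]$emg_effort_scale
      for (ph in list(c(b[["grasp0"]], b[["transport0"]], 0.30),
                      c(b[["release0"]], b[["home0"]], 0.30),
                      c(b[["reach0"]], b[["grasp0"]], 0.15),
                      c(b[["transport0"]], b[["release0"]], 0.15))) {
        inph <- te >= ph[1] & te <= ph[2]
        n <- sum(inph)
        if (n > 4) {
          env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
          x[inph] <- x[inph] + ph[3] * eff * w[ch] * env * stats::rnorm(n)
        }
      }
    }
    pmin(pmax(x, -1), 1)
  }, numeric(length(te)))
  colnames(vals) <- emg_channels
  promet_ts(te, vals, fs)
}

# Ledger: scripted and threshold-consistent boundaries plus injected values.
trial_truth <- function(sched, hand_pieces, ap_pieces, wr_pieces, sh_pieces,
                        cfg, task_id) {
  piece_peak <- function(p) {
    amp <- sqrt((p$x1 - p$x0)^2 + (p$y1 - p$y0)^2 + (p$z1 - p$z0)^2)
    amp * 1.875 / (p$t1 - p$t0)
  }
  hand_pieces$amp <- sqrt((hand_pieces$x1 - hand_pieces$x0)^2 +
                            (hand_pieces$y1 - hand_pieces$y0)^2 +
                            (hand_pieces$z1 - hand_pieces$z0)^2)
  thr_global <- cfg$hand_speed_onset_frac * max(piece_peak(hand_pieces))
  movements <- lapply(1:3, function(m) {
    b <- sched[[m]]$bounds; p <- sched[[m]]$params
    hp <- hand_pieces[hand_pieces$m == m, ]
    reach <- hp[hp$seg == "reach", ]; trans <- hp[hp$seg == "transport", ]
    home <- hp[hp$seg == "home", ]
    thr_win <- cfg$hand_speed_onset_frac * max(piece_peak(hp))
    reach_on <- piece_crossings(reach$t0, reach$t1, reach$amp, thr_global)[1]
    home_off <- piece_crossings(home$t0, home$t1, home$amp, thr_global)[2]
    grasp_on <- piece_crossings(reach$t0, reach$t1, reach$amp, thr_win)[2]
    thr_obj <- cfg$object_speed_onset_frac * piece_peak(trans)
    tr <- piece_crossings(trans$t0, trans$t1, trans$amp, thr_obj)
    home_on <- piece_crossings(home$t0, home$t1, home$amp, thr_win)[1]
    detectable <- data.frame(
      label = phase_order,
      start_s = c(reach_on, grasp_on, tr[1], tr[2], home_on),
      end_s = c(grasp_on, tr[1], tr[2], home_on, home_off))
    scripted <- data.frame(
      label = phase_order,
      start_s = unname(b[1:5]), end_s = unname(b[2:6]))
    list(scripted = scripted, detectable = detectable,
         reach = list(D = reach$amp, T = reach$t1 - reach$t0),
         transport = list(D = trans$amp, T = trans$t1 - trans$t0),
         aperture_adj = base_adj_counts("aperture") + p$extra_ap_adj,
         wrist_adj = base_adj_counts("wrist") + p$extra_wr_adj,
         aperture_excursion = excursion_by_phase(ap_pieces, scripted),
         wrist_excursion = excursion_by_phase(wr_pieces, scripted),
         plateau_s = analytic_plateau(ap_pieces, detectable),
         simultaneity = analytic_simultaneity(wr_pieces, sh_pieces,
                                              detectable, reach_on, home_off))
  })
  list(task_id = task_id, movements = movements)
}

base_adj_counts <- function(which) {
  if (which == "aperture") c(Reach = 1, Grasp = 1, Transport = 0, Release = 1)
  else c(Reach = 1, Grasp = 0, Transport = 1, Release = 0)
}

excursion_by_phase <- function(pieces, scripted) {
  out <- c(Reach = 0, Grasp = 0, Transport = 0, Release = 0)
  for (ph in names(out)) {
    w <- scripted[scripted$label == ph, ]
    inph <- pieces$t0 >= w$start_s - 1e-9 & pieces$t1 <= w$end_s + 1e-9
    out[[ph]] <- sum(abs(pieces$v1[inph] - pieces$v0[inph]))
  }
  out
}

# Continuous-time centered moving average matching the metric definitions
# (the smoothing is part of the metric, so the ledger applies it too). The
# default window is the effective duration of a 0.1 s moving average at the
# 120 Hz kinematic rate (rounded up to an odd 13 samples).
fine_smooth <- function(x, dt, window_s) {
  w <- max(1L, round(window_s / dt))
  if (w %% 2L == 0L) w <- w + 1L
  moving_average(x, w)
}

# Fine-grid evaluation of the plateau conditions on the analytic aperture.
analytic_plateau <- function(ap_pieces, detectable, thresholds = threshold_set(),
                             dt = 5e-4, smooth_s = 13 / 120) {
  rg <- c(detectable$start_s[1], detectable$end_s[2])
  t <- seq(rg[1], rg[2], by = dt)
  a <- fine_smooth(eval_pieces(ap_pieces, t), dt, smooth_s)
  v <- fine_smooth(eval_pieces_deriv(ap_pieces, t), dt, smooth_s)
  ok <- a >= thresholds$plateau_aperture_frac * max(a) &
    abs(v) <= thresholds$plateau_velocity_frac * max(abs(v))
  sum(ok) * dt
}

# The percentage is evaluated on the 120 Hz sample grid the metric sees
# (the speeds themselves stay analytic), since a ratio of sample counts is
# what the metric reports for finite recordings.
analytic_simultaneity <- function(wr_pieces, sh_pieces, detectable,
                                  mov_start, mov_end,
                                  thresholds = threshold_set(), dt = 5e-4,
                                  smooth_s = 13 / 120, fs = 120) {
  tf <- seq(mov_start - smooth_s, mov_end + smooth_s, by = dt)
  ws <- abs(fine_smooth(eval_pieces_deriv(wr_pieces, tf), dt, smooth_s))
  ss <- abs(fine_smooth(eval_pieces_deriv(sh_pieces, tf), dt, smooth_s))
  tk <- (ceiling(mov_start * fs):floor(mov_end * fs)) / fs
  at_k <- function(v) stats::approx(tf, v, xout = tk)$y
  wsk <- at_k(ws); ssk <- at_k(ss)
  sim <- wsk > thresholds$simultaneity_frac * max(wsk) &
    ssk > thresholds$simultaneity_frac * max(ssk)
  out <- c(Reach = NA_real_, Transport = NA_real_)
  for (ph in names(out)) {
    w <- detectable[detectable$label == ph, ]
    inph <- tk >= w$start_s - 1e-9 & tk <= w$end_s + 1e-9
    out[[ph]] <- 100 * sum(sim & inph) / sum(inph)
  }
  out
}

#' Ground-truth segmentation of a generated trial
#'
#' Converts a [generate_trial()] ledger into a `promet_seg`, usable wherever
#' a detected segmentation is (e.g. to compute metrics against scripted
#' boundaries).
#'
#' @param truth Ledger from [generate_trial()].
#' @param which `"detectable"` (default) or `"scripted"` boundaries.
#' @return A `promet_seg`.
#' @export
truth_segmentation <- function(truth, which = c("detectable", "scripted")) {
  which <- match.arg(which)
  movements <- lapply(truth$movements, function(m) {
    ph <- m[[which]]
    list(start_s = ph$start_s[1], end_s = ph$end_s[5], phases = ph,
         segments = derive_segments(ph))
  })
  new_segmentation(movements)
}
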