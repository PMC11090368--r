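#' Metric configuration
#'
#' @param n_norm_points Number of points for time normalization of hand
#'   trajectories (101: 0%, 1%, ..., 100% of the movement segment).
#' @param velocity_lowpass_hz Zero-phase low-pass cutoff applied to hand
#'   positions before differentiation in velocity metrics (peak speeds are
#'   noise-sensitive).
#' @return Object of class `promet_metriccfg`.
#' @export
metric_config <- function(n_norm_points = 101, velocity_lowpass_hz = 6) {
  if (n_norm_points < 2) stop_promet("bad_config", "n_norm_points must be >= 2")
  structure(list(n_norm_points = as.integer(n_norm_points),
                 velocity_lowpass_hz = velocity_lowpass_hz),
            class = "promet_metriccfg")
}

#' Task success rate
#'
#' Percent of possible trial attempts that were error-free.
#'
#' @param n_error_free Number of error-free trials.
#' @param n_attempts Number of possible trial attempts (>= 1).
#' @return Percent in \[0, 100\].
#' @export
success_rate <- function(n_error_free, n_attempts) {
  if (n_attempts < 1) stop_promet("bad_count", "need at least one attempt")
  if (n_error_free > n_attempts || n_error_free < 0) {
    stop_promet("bad_count", "error-free count must lie in [0, attempts]")
  }
  100 * n_error_free / n_attempts
}

#' Trial duration
#'
#' End of the trial's last phase minus start of its first phase, in seconds.
#'
#' @param seg A `promet_seg`.
#' @return Seconds.
#' @export
trial_duration <- function(seg) {
  validate_segmentation(seg)
  last <- seg$movements[[3]]$phases
  first <- seg$movements[[1]]$phases
  last$end_s[5] - first$start_s[1]
}

#' Phase duration and relative phase duration
#'
#' The movement duration used as the denominator is the Reach through
#' Release span (Home excluded).
#'
#' @param seg A `promet_seg`.
#' @param movement Movement number 1-3.
#' @param phase One of Reach, Grasp, Transport, Release.
#' @return Seconds (`phase_duration`) or percent (`relative_phase_duration`).
#' @export
phase_duration <- function(seg, movement, phase) {
  if (!phase %in% analysis_phases) {
    stop_promet("bad_level", "'%s' is not an analyzed phase", phase)
  }
  p <- seg_phase(seg, movement, phase)
  p$end_s - p$start_s
}

#' @rdname phase_duration
#' @export
relative_phase_duration <- function(seg, movement, phase) {
  d <- phase_duration(seg, movement, phase)
  ph <- seg$movements[[movement]]$phases
  md <- ph$end_s[ph$label == "Release"] - ph$start_s[ph$label == "Reach"]
  if (md <= 0) stop_promet("bad_segmentation", "zero movement duration")
  100 * d / md
}

# Hand positions (n x 3 matrix) over a window of the kinematics stream.
hand_positions <- function(trial, window) {
  k <- ts_window(trial$kinematics, window$start_s[1], window$end_s[1])
  list(t = k$t, fs = k$fs,
       xyz = cbind(ts_channel(k, "hand_x"), ts_channel(k, "hand_y"),
                   ts_channel(k, "hand_z")))
}

#' Peak hand velocity over a movement segment
#'
#' Maximum of the 3D hand speed (Euclidean norm of the velocity vector)
#' within the segment. Positions are low-passed (zero phase) at
#' `cfg$velocity_lowpass_hz` before central-difference differentiation.
#'
#' @param xyz Numeric n x 3 matrix of hand positions (mm), or a
#'   [trial_recording()] together with `window`.
#' @param fs Sampling rate in Hz (when `xyz` is a matrix).
#' @param cfg A [metric_config()].
#' @param window Optional segment window (`data.frame` with
#'   `start_s`/`end_s`) when a trial is supplied.
#' @return Peak speed in mm/s.
#' @export
peak_hand_velocity <- function(xyz, fs = 120, cfg = metric_config(),
                               window = NULL) {
  if (inherits(xyz, "promet_trial")) {
    hp <- hand_positions(xyz, window)
    xyz <- hp$xyz; fs <- hp$fs
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop_promet("too_few_samples", "need >= 3 samples")
  sm <- if (is.null(cfg$velocity_lowpass_hz)) xyz else {
    apply(xyz, 2, lowpass_zero_phase, fs = fs, cutoff_hz = cfg$velocity_lowpass_hz)
  }
  vel <- apply(sm, 2, time_derivative, fs = fs)
  max(sqrt(rowSums(vel^2)))
}

#' Hand distance travelled over a movement segment
#'
#' Sum of Euclidean distances between successive hand positions.
#'
#' @inheritParams peak_hand_velocity
#' @return Distance in mm.
#' @export
hand_distance_travelled <- function(xyz, window = NULL) {
  if (inherits(xyz, "promet_trial")) xyz <- hand_positions(xyz, window)$xyz
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop_promet("too_few_samples", "need >= 2 samples")
  sum(sqrt(rowSums(diff(xyz)^2)))
}

# Linear time-normalization of an n x 3 trajectory to m points over 0-100%.
time_normalize_xyz <- function(xyz, m) {
  n <- nrow(xyz)
  u <- seq(0, 1, length.out = m)
  x0 <- seq(0, 1, length.out = n)
  vapply(1:3, function(j) stats::approx(x0, xyz[, j], xout = u)$y, numeric(m))
}

#' Between-trial hand trajectory variability
#'
#' For one participant and one movement-segment type: each trial's x, y, z
#' trajectory is linearly time-normalized to `cfg$n_norm_points` points over
#' 0-100% of the segment; at each point the sample standard deviation
#' (n - 1 denominator) of each coordinate across trials is taken; the three
#' SDs are averaged per point; the maximum over points is returned.
#'
#' @param trajectories List (length >= 2) of n_i x 3 position matrices, one
#'   per trial of the same segment type.
#' @param cfg A [metric_config()].
#' @return Variability in mm.
#' @export
hand_trajectory_variability <- function(trajectories, cfg = metric_config()) {
  if (length(trajectories) < 2L) {
    stop_promet("too_few_trials", "need >= 2 trials, have %d", length(trajectories))
  }
  m <- cfg$n_norm_points
  norm <- lapply(trajectories, function(x) time_normalize_xyz(as.matrix(x), m))
  per_axis_sd <- vapply(1:3, function(j) {
    mat <- vapply(norm, function(z) z[, j], numeric(m))  # m x trials
    apply(mat, 1, stats::sd)
  }, numeric(m))
  max(rowMeans(per_axis_sd))
}
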