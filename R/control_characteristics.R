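#' Threshold set for plateau and simultaneity detection
#'
#' Relative thresholds used by [grip_aperture_plateau()] (aperture above 90%
#' of the segment maximum while aperture speed is below 10% of the segment
#' maximum) and [simultaneous_wrist_shoulder()] (both angular speeds above
#' 10% of their movement maxima).
#'
#' @param plateau_aperture_frac,plateau_velocity_frac,simultaneity_frac
#'   Fractions in (0, 1).
#' @return Object of class `promet_thresholds`.
#' @export
threshold_set <- function(plateau_aperture_frac = 0.90,
                          plateau_velocity_frac = 0.10,
                          simultaneity_frac = 0.10) {
  x <- list(plateau_aperture_frac = plateau_aperture_frac,
            plateau_velocity_frac = plateau_velocity_frac,
            simultaneity_frac = simultaneity_frac)
  if (any(unlist(x) <= 0 | unlist(x) >= 1)) {
    stop_promet("bad_config", "thresholds must lie in (0, 1)")
  }
  structure(x, class = "promet_thresholds")
}

#' Total excursion of a signal over a window
#'
#' Sum of absolute differences between successive samples: total grip
#' aperture movement (mm) or total wrist rotation movement (deg).
#'
#' @param x Numeric vector of samples within the phase window.
#' @return Total variation in the units of `x`.
#' @export
total_excursion <- function(x) {
  if (length(x) < 2L) stop_promet("too_few_samples", "need >= 2 samples")
  sum(abs(diff(x)))
}

# Dead-banded sign of a smoothed velocity trace: |v| <= deadband -> 0.
velocity_signs <- function(x, fs, cfg) {
  v <- time_derivative(x, fs)
  v <- moving_average(v, smooth_samples(cfg$smooth_window_s, fs))
  db <- cfg$deadband_frac * max(abs(v))
  s <- sign(v)
  s[abs(v) <= db] <- 0
  s
}

#' Count grip-aperture or wrist-rotation adjustments
#'
#' The signal's velocity is computed, smoothed with a centered moving
#' average, and dead-banded (samples with magnitude at most
#' `deadband_frac` of the in-window peak count as zero). Transitions of the
#' sign sequence of the kinds 0 to +, 0 to -, - to +, and + to - are
#' counted; transitions into 0 are not.
#'
#' @param x Numeric vector of aperture (mm) or wrist angle (deg) samples
#'   within the phase window.
#' @param fs Sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return Object of class `promet_adjustments` with `count` and
#'   `transitions` (data.frame time index, from, to).
#' @export
count_adjustments <- function(x, fs = 120, cfg = preprocess_config()) {
  if (length(x) < 3L) stop_promet("too_few_samples", "need >= 3 samples")
  s <- velocity_signs(x, fs, cfg)
  counted <- count_sign_transitions(s)
  structure(list(count = nrow(counted), transitions = counted, signs = s),
            class = "promet_adjustments")
}

# Transition counting on a -1/0/+1 sign sequence (shared with the test
# oracle's rule statement; kept as one tight loop-free primitive).
count_sign_transitions <- function(s) {
  n <- length(s)
  if (n < 2L) {
    return(data.frame(index = integer(), from = numeric(), to = numeric()))
  }
  from <- s[-n]; to <- s[-1]
  hit <- (from == 0 & to != 0) | (from == -1 & to == 1) | (from == 1 & to == -1)
  data.frame(index = which(hit) + 1L, from = from[hit], to = to[hit])
}

#' @export
print.promet_adjustments <- function(x, ...) {
  cat(sprintf("<promet_adjustments> %d transition(s)\n", x$count))
  invisible(x)
}

#' Grip aperture plateau duration over the Reach-Grasp segment
#'
#' Aperture and aperture velocity are smoothed with a centered moving
#' average; plateau samples satisfy smoothed aperture >=
#' `plateau_aperture_frac` of the segment maximum AND smoothed |velocity| <=
#' `plateau_velocity_frac` of the segment maximum |velocity| (inclusive
#' comparisons, so a perfectly still open hand counts as plateau). Returns
#' the summed duration of plateau samples.
#'
#' @param aperture Numeric vector of aperture samples over the Reach-Grasp
#'   segment (mm).
#' @param fs Sampling rate in Hz.
#' @param thresholds A [threshold_set()].
#' @param cfg A [preprocess_config()].
#' @return Plateau duration in seconds.
#' @export
grip_aperture_plateau <- function(aperture, fs = 120,
                                  thresholds = threshold_set(),
                                  cfg = preprocess_config()) {
  if (length(aperture) < 3L) stop_promet("too_few_samples", "need >= 3 samples")
  w <- smooth_samples(cfg$smooth_window_s, fs)
  a <- moving_average(aperture, w)
  v <- moving_average(time_derivative(aperture, fs), w)
  ok <- a >= thresholds$plateau_aperture_frac * max(a) &
    abs(v) <= thresholds$plateau_velocity_frac * max(abs(v))
  sum(ok) / fs
}

#' Percent of a phase with simultaneous wrist and shoulder movement
#'
#' Wrist-rotation and shoulder-flexion/extension angular velocities are
#' smoothed and rectified; a sample is simultaneous when wrist speed exceeds
#' `simultaneity_frac` of the movement's maximum wrist speed AND shoulder
#' speed exceeds the same fraction of the movement's maximum shoulder speed.
#' Returns 100 x simultaneous duration / phase duration. Intended for
#' phases that require both wrist rotation and shoulder movement (Reach and
#' Transport of the clothespin tasks).
#'
#' @param wrist,shoulder Angle vectors (deg) spanning the whole movement.
#' @param t Time vector for `wrist`/`shoulder` (trial seconds).
#' @param phase_window `c(start_s, end_s)` of the phase within the movement.
#' @param fs Sampling rate in Hz.
#' @param thresholds A [threshold_set()].
#' @param cfg A [preprocess_config()].
#' @return Percent in \[0, 100\].
#' @export
simultaneous_wrist_shoulder <- function(wrist, shoulder, t, phase_window,
                                        fs = 120,
                                        thresholds = threshold_set(),
                                        cfg = preprocess_config()) {
  if (diff(range(phase_window)) <= 0) {
    stop_promet("bad_window", "zero-duration phase")
  }
  w <- smooth_samples(cfg$smooth_window_s, fs)
  ws <- abs(moving_average(time_derivative(wrist, fs), w))
  ss <- abs(moving_average(time_derivative(shoulder, fs), w))
  sim <- ws > thresholds$simultaneity_frac * max(ws) &
    ss > thresholds$simultaneity_frac * max(ss)
  inph <- t >= phase_window[1] - 1e-9 & t <= phase_window[2] + 1e-9
  if (!any(inph)) stop_promet("empty_window", "phase window contains no samples")
  100 * sum(sim & inph) / sum(inph)
}

#' Total muscle activity over a phase
#'
#' Pipeline: (1) high-pass + notch filter the 8-channel EMG and rectify;
#' (2) subtract each channel's rest-class mean rectified value; (3) sum
#' across channels; (4) take the linear envelope (zero-phase low-pass at
#' `cfg$envelope_lowpass_hz`); (5) sum the envelope samples falling inside
#' the phase window. Negative post-subtraction values are kept unless
#' `cfg$clip_negative_activity` is set.
#'
#' @param emg `promet_ts` with 8 channels spanning at least the phase.
#' @param rest A [rest_reference()].
#' @param phase_window `c(start_s, end_s)` in trial seconds.
#' @param cfg A [preprocess_config()].
#' @param prefiltered Set TRUE when `emg` has already been through
#'   [filter_emg()].
#' @return Dimensionless activity (sum of envelope samples).
#' @export
total_muscle_activity <- function(emg, rest, phase_window,
                                  cfg = preprocess_config(),
                                  prefiltered = FALSE) {
  if (!inherits(rest, "promet_rest")) {
    stop_promet("bad_rest_reference", "rest reference required")
  }
  f <- if (prefiltered) emg else filter_emg(emg, cfg)
  rect <- abs(f$values[, emg_channels, drop = FALSE])
  norm <- sweep(rect, 2, rest$channel_means)
  if (cfg$clip_negative_activity) norm[norm < 0] <- 0
  summed <- rowSums(norm)
  env <- lowpass_zero_phase(summed, f$fs, cfg$envelope_lowpass_hz)
  inph <- f$t >= phase_window[1] - 1e-9 & f$t <= phase_window[2] + 1e-9
  if (!any(inph)) stop_promet("empty_window", "phase window contains no EMG samples")
  sum(env[inph])
}
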