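#' Signal-conditioning configuration
#'
#' Collects the signal-processing constants used across the metric pipeline:
#' EMG high-pass cutoff (20 Hz, movement-artifact removal), EMG notch
#' frequency (60 Hz mains), analysis window length and offset (160 ms / 40 ms),
#' the moving-average smoothing window used for velocity-based metrics
#' (0.1 s), the linear-envelope low-pass cutoff (6 Hz), and the dead-band
#' fraction of peak speed below which a velocity sample is treated as zero
#' when counting adjustments (0.01).
#'
#' @param emg_highpass_hz High-pass cutoff in Hz.
#' @param emg_notch_hz Notch frequency in Hz.
#' @param notch_q Quality factor of the notch (bandwidth = f0/Q).
#' @param window_ms,window_offset_ms Analysis window length and stride in ms.
#' @param smooth_window_s Moving-average window in seconds.
#' @param envelope_lowpass_hz Envelope low-pass cutoff in Hz.
#' @param deadband_frac Fraction of peak speed treated as zero velocity.
#' @param clip_negative_activity Clip negative baseline-subtracted EMG at 0
#'   in [total_muscle_activity()] (default FALSE, the literal reading).
#' @return Object of class `promet_prep`.
#' @export
preprocess_config <- function(emg_highpass_hz = 20, emg_notch_hz = 60,
                              notch_q = 30, window_ms = 160,
                              window_offset_ms = 40, smooth_window_s = 0.1,
                              envelope_lowpass_hz = 6, deadband_frac = 0.01,
                              clip_negative_activity = FALSE) {
  x <- list(emg_highpass_hz = emg_highpass_hz, emg_notch_hz = emg_notch_hz,
            notch_q = notch_q, window_ms = window_ms,
            window_offset_ms = window_offset_ms,
            smooth_window_s = smooth_window_s,
            envelope_lowpass_hz = envelope_lowpass_hz,
            deadband_frac = deadband_frac,
            clip_negative_activity = isTRUE(clip_negative_activity))
  num <- x[setdiff(names(x), "clip_negative_activity")]
  if (any(!vapply(num, function(v) is.numeric(v) && v > 0, logical(1)))) {
    stop_promet("bad_config", "all preprocessing values must be positive")
  }
  if (window_offset_ms > window_ms) {
    stop_promet("bad_config", "window offset must not exceed window length")
  }
  structure(x, class = "promet_prep")
}

# Odd moving-average length in samples for a window of `sec` seconds at fs.
smooth_samples <- function(sec, fs) {
  w <- max(1L, round(sec * fs))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

#' Zero-phase high-pass and notch filtering of multi-channel EMG
#'
#' Applies a 4th-order Butterworth high-pass at `cfg$emg_highpass_hz` and a
#' second-order IIR notch at `cfg$emg_notch_hz` (quality factor
#' `cfg$notch_q`), both forward-backward (zero phase) per channel.
#'
#' @param raw A `promet_ts` (any number of channels).
#' @param cfg A [preprocess_config()].
#' @return A `promet_ts` of the same length.
#' @export
filter_emg <- function(raw, cfg = preprocess_config()) {
  validate_ts(raw)
  if (raw$fs < 2 * cfg$emg_notch_hz) {
    stop_promet("nyquist_violation",
                "fs = %g Hz cannot represent a %g Hz notch (need fs >= %g)",
                raw$fs, cfg$emg_notch_hz, 2 * cfg$emg_notch_hz)
  }
  hp <- signal::butter(4, cfg$emg_highpass_hz / (raw$fs / 2), type = "high")
  nt <- notch_biquad(cfg$emg_notch_hz, raw$fs, cfg$notch_q)
  out <- apply(raw$values, 2, function(v) {
    v <- signal::filtfilt(hp, v)
    signal::filtfilt(nt, v)
  })
  out <- matrix(out, nrow = nrow(raw$values),
                dimnames = dimnames(raw$values))
  structure(list(t = raw$t, values = out, fs = raw$fs), class = "promet_ts")
}

# Standard constrained biquad notch (unit gain at DC and Nyquist).
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Previous-neighbour (sample-and-hold) upsampling
#'
#' Each original sample is repeated `target_fs / fs` times, aligning a
#' low-rate stream (e.g. 50 Hz accelerometer or motor data) with a faster
#' one. The ratio must be an integer.
#'
#' @param series A `promet_ts`.
#' @param target_fs Target sampling rate in Hz.
#' @return A `promet_ts` at `target_fs`.
#' @export
upsample_hold <- function(series, target_fs) {
  validate_ts(series)
  r <- target_fs / series$fs
  if (abs(r - round(r)) > 1e-9 || r < 1) {
    stop_promet("bad_ratio", "target fs must be an integer multiple of fs")
  }
  r <- as.integer(round(r))
  n <- length(series$t)
  idx <- rep(seq_len(n), each = r)
  structure(list(t = series$t[1L] + (seq_len(n * r) - 1L) / target_fs,
                 values = series$values[idx, , drop = FALSE],
                 fs = target_fs), class = "promet_ts")
}

#' Linear-interpolation upsampling
#'
#' Resamples onto a uniform grid at `target_fs` spanning the original time
#' range; values are linear interpolants, endpoints preserved.
#'
#' @inheritParams upsample_hold
#' @return A `promet_ts` at `target_fs`.
#' @export
upsample_linear <- function(series, target_fs) {
  validate_ts(series)
  n <- length(series$t)
  if (n < 2L) stop_promet("too_few_samples", "need >= 2 samples to interpolate")
  t_new <- seq(series$t[1L], series$t[n], by = 1 / target_fs)
  vals <- apply(series$values, 2, function(v) {
    stats::approx(series$t, v, xout = t_new)$y
  })
  vals <- matrix(vals, nrow = length(t_new), dimnames = list(NULL, colnames(series$values)))
  structure(list(t = t_new, values = vals, fs = target_fs), class = "promet_ts")
}

#' Fixed-length analysis windows with constant stride
#'
#' Splits a series into windows of `cfg$window_ms` milliseconds advanced by
#' `cfg$window_offset_ms`; window length `L = round(window_ms * fs / 1000)`,
#' stride `S = round(offset_ms * fs / 1000)`, count `floor((N - L) / S) + 1`.
#'
#' @param series A `promet_ts`.
#' @param cfg A [preprocess_config()].
#' @return List with `length`, `stride`, `starts` (start indices) and
#'   `windows` (list of value matrices, one per window).
#' @export
window_signal <- function(series, cfg = preprocess_config()) {
  validate_ts(series)
  L <- as.integer(round(cfg$window_ms * series$fs / 1000))
  S <- as.integer(round(cfg$window_offset_ms * series$fs / 1000))
  n <- length(series$t)
  if (n < L) {
    stop_promet("too_few_samples",
                "series of %d samples shorter than one %d-sample window", n, L)
  }
  starts <- seq.int(1L, n - L + 1L, by = S)
  list(length = L, stride = S, starts = starts,
       windows = lapply(starts, function(s) {
         series$values[s:(s + L - 1L), , drop = FALSE]
       }))
}

#' Centered moving average with truncated edges
#'
#' Centered mean over an odd window; at the edges the window shrinks to the
#' available samples, so output length equals input length and constants
#' pass through unchanged.
#'
#' @param x Numeric vector.
#' @param window_samples Odd positive window length in samples.
#' @return Smoothed numeric vector.
#' @export
moving_average <- function(x, window_samples) {
  if (window_samples < 1 || window_samples %% 2 == 0) {
    stop_promet("bad_window", "window must be a positive odd sample count")
  }
  n <- length(x)
  if (window_samples == 1L || n == 0L) return(x)
  h <- (window_samples - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Numerical time derivative
#'
#' Central differences in the interior, one-sided differences at the
#' endpoints; returns units per second.
#'
#' @param x Numeric vector sampled uniformly at `fs`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of the same length.
#' @export
time_derivative <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stop_promet("too_few_samples", "need >= 3 samples to differentiate")
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d
}

# Zero-phase low-pass used for envelopes and pre-differentiation smoothing.
# Odd-reflection padding suppresses filtfilt end transients, which would
# otherwise dwarf genuine peaks on signals with large endpoint offsets.
lowpass_zero_phase <- function(x, fs, cutoff_hz, order = 2) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  n <- length(x)
  p <- min(n - 1L, max(24L, 3L * round(fs / cutoff_hz)))
  if (p < 1L) return(signal::filtfilt(bf, x))
  pre <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(p + 1L):(p + n)]
}

#' Polynomial calibration from device motor positions to kinematic units
#'
#' Least-squares polynomial fit mapping raw motor positions to a
#' motion-capture-derived kinematic reference (degree 3 for hand motor to
#' grip aperture, degree 2 for wrist motor to wrist rotation angle). Motor
#' data should first be upsampled to the kinematic rate with
#' [upsample_linear()] so the two vectors are aligned sample-for-sample.
#'
#' @param motor Numeric vector of motor positions (raw units).
#' @param reference Numeric vector of the same length in target units.
#' @param degree Polynomial degree.
#' @param source_units,target_units Unit labels carried along.
#' @return Object of class `promet_cal` with `degree` and `coefficients`
#'   (intercept first).
#' @export
fit_motor_calibration <- function(motor, reference, degree,
                                  source_units = "raw", target_units = "") {
  ok <- is.finite(motor) & is.finite(reference)
  motor <- motor[ok]; reference <- reference[ok]
  if (length(motor) <= degree) {
    stop_promet("too_few_samples",
                "need more than degree (%d) points, have %d", degree, length(motor))
  }
  if (stats::sd(motor) < 1e-12) {
    stop_promet("degenerate_input", "motor values are constant; cannot calibrate")
  }
  fit <- stats::lm(reference ~ stats::poly(motor, degree, raw = TRUE))
  structure(list(degree = as.integer(degree),
                 coefficients = unname(stats::coef(fit)),
                 source_units = source_units, target_units = target_units),
            class = "promet_cal")
}

#' @rdname fit_motor_calibration
#' @param cal A `promet_cal`.
#' @param x Motor positions to transform.
#' @return `apply_calibration`: predicted kinematic values.
#' @export
apply_calibration <- function(cal, x) {
  stopifnot(inherits(cal, "promet_cal"))
  drop(outer(x, 0:cal$degree, `^`) %*% cal$coefficients)
}

#' Grip aperture as thumb-index marker distance
#'
#' Per-sample Euclidean distance between the thumb and index marker
#' positions; NaN coordinates propagate to NaN apertures at those samples
#' only.
#'
#' @param thumb,index Numeric matrices (n x 3) of marker positions in mm.
#' @return Numeric vector of apertures in mm.
#' @export
aperture_from_markers <- function(thumb, index) {
  thumb <- as.matrix(thumb); index <- as.matrix(index)
  stopifnot(ncol(thumb) == 3L, ncol(index) == 3L, nrow(thumb) == nrow(index))
  sqrt(rowSums((thumb - index)^2))
}
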