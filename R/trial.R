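#' One functional-task trial: synchronized signals plus identifiers
#'
#' Container for all signals of a single object-relocation trial:
#' kinematics at 120 Hz (hand position in mm, grip aperture in mm, wrist
#' rotation and shoulder flexion/extension angles in degrees), task-object
#' positions at 120 Hz, 8-channel surface EMG in \[-1, 1\] at 200 Hz, and
#' optionally raw device motor positions at 50 Hz.
#'
#' @param participant_id,controller_id Labels.
#' @param task_id One of `"PASTA"`, `"RCRT_UP"`, `"RCRT_DOWN"`, `"CUSTOM"`.
#' @param trial_index Integer >= 1.
#' @param error_free Logical; whether the trial was executed without task
#'   errors (an observational input, not computed).
#' @param kinematics `promet_ts` at 120 Hz with channels `hand_x`, `hand_y`,
#'   `hand_z`, `aperture`, `wrist_rot`, `shoulder_fe`.
#' @param objects `promet_ts` at 120 Hz with channels `obj<k>_x/y/z`.
#' @param emg `promet_ts` at 200 Hz with channels `emg_1` .. `emg_8`.
#' @param motor Optional `promet_ts` at 50 Hz with `hand_motor`, `wrist_motor`.
#' @param max_na_frac Maximum tolerated fraction of NaN samples in any
#'   required kinematic channel (default 0.05).
#' @return A validated object of class `promet_trial`.
#' @export
trial_recording <- function(participant_id, controller_id, task_id,
                            trial_index, error_free,
                            kinematics, objects, emg, motor = NULL,
                            max_na_frac = 0.05) {
  x <- structure(list(
    participant_id = as.character(participant_id),
    controller_id = as.character(controller_id),
    task_id = match.arg(task_id, c("PASTA", "RCRT_UP", "RCRT_DOWN", "CUSTOM")),
    trial_index = as.integer(trial_index),
    error_free = isTRUE(error_free),
    kinematics = kinematics, objects = objects, emg = emg, motor = motor
  ), class = "promet_trial")
  validate_trial(x, max_na_frac = max_na_frac)
  x
}

kin_channels <- c("hand_x", "hand_y", "hand_z", "aperture",
                  "wrist_rot", "shoulder_fe")
emg_channels <- paste0("emg_", 1:8)

#' @rdname trial_recording
#' @param x Object to validate.
#' @export
validate_trial <- function(x, max_na_frac = 0.05) {
  stopifnot(inherits(x, "promet_trial"))
  if (x$trial_index < 1L) stop_promet("bad_index", "trial_index must be >= 1")
  for (s in c("kinematics", "objects", "emg")) validate_ts(x[[s]])
  miss <- setdiff(kin_channels, colnames(x$kinematics$values))
  if (length(miss)) {
    stop_promet("missing_column", "kinematics lacks channel(s): %s",
                paste(miss, collapse = ", "))
  }
  for (ch in kin_channels) {
    frac <- mean(!is.finite(ts_channel(x$kinematics, ch)))
    if (frac > max_na_frac) {
      stop_promet("too_many_missing",
                  "channel '%s' has %.1f%% missing samples (limit %.1f%%)",
                  ch, 100 * frac, 100 * max_na_frac)
    }
  }
  ap <- ts_channel(x$kinematics, "aperture")
  if (any(ap < -1e-9, na.rm = TRUE)) {
    stop_promet("negative_aperture", "grip aperture must be nonnegative")
  }
  miss <- setdiff(emg_channels, colnames(x$emg$values))
  if (length(miss)) {
    stop_promet("missing_column", "emg lacks channel(s): %s",
                paste(miss, collapse = ", "))
  }
  if (any(abs(x$emg$values) > 1 + 1e-9, na.rm = TRUE)) {
    stop_promet("emg_out_of_range", "EMG values must lie within [-1, 1]")
  }
  # kinematics and objects share one time base; emg overlaps the kinematic span
  if (length(x$objects$t) != length(x$kinematics$t) ||
      max(abs(x$objects$t - x$kinematics$t)) > 1e-9) {
    stop_promet("timebase_mismatch",
                "objects and kinematics must share one time base")
  }
  if (x$emg$t[1L] > x$kinematics$t[length(x$kinematics$t)] ||
      x$emg$t[length(x$emg$t)] < x$kinematics$t[1L]) {
    stop_promet("timebase_mismatch", "EMG span does not overlap kinematics")
  }
  if (!is.null(x$motor)) validate_ts(x$motor)
  invisible(x)
}

#' @export
print.promet_trial <- function(x, ...) {
  cat(sprintf("<promet_trial> %s / %s / %s trial %d (%s), %.2f s\n",
              x$participant_id, x$controller_id, x$task_id, x$trial_index,
              if (x$error_free) "error-free" else "with errors",
              ts_duration(x$kinematics)))
  invisible(x)
}

#' Rest-class EMG reference
#'
#' Per-channel mean rectified EMG of the rest wrist position recorded with
#' the elbow bent at 90 degrees, used to baseline-normalize the total
#' muscle activity metric.
#'
#' @param channel_means Numeric vector of 8 nonnegative values.
#' @return Object of class `promet_rest`.
#' @export
rest_reference <- function(channel_means) {
  channel_means <- as.numeric(channel_means)
  if (length(channel_means) != 8L) {
    stop_promet("bad_rest_reference", "rest reference needs exactly 8 values")
  }
  if (any(!is.finite(channel_means)) || any(channel_means < 0)) {
    stop_promet("bad_rest_reference", "rest means must be finite and >= 0")
  }
  structure(list(channel_means = channel_means), class = "promet_rest")
}

#' Compute a rest reference from a rest-class EMG recording
#'
#' Rectifies each channel of a rest recording (optionally after the standard
#' filtering) and takes per-channel means.
#'
#' @param emg `promet_ts` with 8 channels of rest-class EMG.
#' @param cfg A [preprocess_config()]; when supplied the EMG is filtered
#'   before rectification, matching the metric pipeline.
#' @return A [rest_reference()].
#' @export
rest_reference_from_emg <- function(emg, cfg = preprocess_config()) {
  x <- if (is.null(cfg)) emg else filter_emg(emg, cfg)
  rest_reference(colMeans(abs(x$values))[emg_channels])
}

metric_levels <- c("controller", "task", "trial", "movement",
                   "movement_segment", "phase")
analysis_phases <- c("Reach", "Grasp", "Transport", "Release")
segment_labels <- c("Reach-Grasp", "Transport-Release")

#' Construct rows of the metric table
#'
#' A metric record holds one metric value at one analysis level. The six
#' levels are controller, task, trial, movement, movement segment and phase;
#' phase-level records name one of Reach/Grasp/Transport/Release and
#' segment-level records one of Reach-Grasp/Transport-Release.
#'
#' @param participant_id,controller_id,task_id Labels.
#' @param metric Metric name.
#' @param level One of `r paste(metric_levels, collapse = ", ")`.
#' @param value Numeric value.
#' @param units Unit label.
#' @param trial_index Trial number or `NA`.
#' @param movement Movement number 1-3 or `NA`.
#' @param phase_or_segment Phase / segment label or `NA`.
#' @return One-row data.frame in the canonical metric-table schema.
#' @export
metric_record <- function(participant_id, controller_id, task_id, metric,
                          level, value, units = "", trial_index = NA,
                          movement = NA, phase_or_segment = NA) {
  level <- match.arg(level, metric_levels)
  if (level == "phase" && !phase_or_segment %in% analysis_phases) {
    stop_promet("bad_level", "phase-level records need a phase in %s",
                paste(analysis_phases, collapse = "/"))
  }
  if (level == "movement_segment" && !phase_or_segment %in% segment_labels) {
    stop_promet("bad_level", "segment-level records need one of %s",
                paste(segment_labels, collapse = "/"))
  }
  data.frame(participant_id = as.character(participant_id),
             controller_id = as.character(controller_id),
             task_id = as.character(task_id),
             metric = as.character(metric), level = level,
             trial_index = as.integer(trial_index),
             movement = as.integer(movement),
             phase_or_segment = as.character(phase_or_segment),
             value = as.numeric(value), units = as.character(units),
             stringsAsFactors = FALSE)
}

validate_metric_table <- function(df) {
  need <- c("participant_id", "controller_id", "task_id", "metric", "level",
            "trial_index", "movement", "phase_or_segment", "value", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_promet("missing_column", "metric table lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(df$level), metric_levels)
  if (length(bad)) {
    stop_promet("bad_level", "unknown analysis level(s): %s",
                paste(bad, collapse = ", "))
  }
  ph <- df$phase_or_segment[df$level == "phase"]
  if (any(!ph %in% analysis_phases)) {
    stop_promet("bad_level", "phase-level rows must name one of %s",
                paste(analysis_phases, collapse = "/"))
  }
  sg <- df$phase_or_segment[df$level == "movement_segment"]
  if (any(!sg %in% segment_labels)) {
    stop_promet("bad_level", "segment-level rows must name one of %s",
                paste(segment_labels, collapse = "/"))
  }
  invisible(df)
}
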