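#' Compute the full metric table for one trial
#'
#' Runs every applicable task-performance and control-characteristics
#' metric at its analysis level: trial duration (trial level); phase and
#' relative phase durations, grip-aperture and wrist-rotation excursions,
#' adjustment counts and total muscle activity (phase level, per movement);
#' peak hand velocity, hand distance travelled and grip-aperture plateau
#' (movement-segment level); simultaneous wrist-shoulder movement (Reach
#' and Transport phases of the clothespin tasks only). Between-trial
#' metrics (success rate, hand trajectory variability) live in
#' [compute_session_metrics()].
#'
#' @param trial A [trial_recording()].
#' @param seg A `promet_seg` (detected via [segment_trial()] or supplied).
#' @param rest A [rest_reference()] (omit to skip muscle activity).
#' @param cfg A [preprocess_config()].
#' @param thresholds A [threshold_set()].
#' @param mcfg A [metric_config()].
#' @return Metric-table data.frame (one [metric_record()] per row).
#' @export
compute_trial_metrics <- function(trial, seg = NULL, rest = NULL,
                                  cfg = preprocess_config(),
                                  thresholds = threshold_set(),
                                  mcfg = metric_config()) {
  if (is.null(seg)) seg <- segment_trial(trial)
  validate_segmentation(seg)
  fs <- trial$kinematics$fs
  rec <- function(...) metric_record(trial$participant_id, trial$controller_id,
                                     trial$task_id, ..., trial_index = trial$trial_index)
  rows <- list(rec("trial_duration", "trial", trial_duration(seg), "s"))
  env <- NULL
  if (!is.null(rest)) {
    femg <- filter_emg(trial$emg, cfg)
    env <- activity_envelope(femg, rest, cfg)
  }
  simultaneity_tasks <- c("RCRT_UP", "RCRT_DOWN")
  wrist <- ts_channel(trial$kinematics, "wrist_rot")
  shoulder <- ts_channel(trial$kinematics, "shoulder_fe")
  aperture <- ts_channel(trial$kinematics, "aperture")
  for (m in 1:3) {
    mw <- c(seg$movements[[m]]$start_s, seg$movements[[m]]$end_s)
    for (ph in analysis_phases) {
      w <- seg_phase(seg, m, ph)
      sel <- trial$kinematics$t >= w$start_s - 1e-9 &
        trial$kinematics$t <= w$end_s + 1e-9
      ap <- aperture[sel]; wr <- wrist[sel]
      rows <- c(rows, list(
        rec("phase_duration", "phase", phase_duration(seg, m, ph), "s",
            movement = m, phase_or_segment = ph),
        rec("relative_phase_duration", "phase",
            relative_phase_duration(seg, m, ph), "%",
            movement = m, phase_or_segment = ph),
        rec("aperture_excursion", "phase", total_excursion(ap), "mm",
            movement = m, phase_or_segment = ph),
        rec("wrist_excursion", "phase", total_excursion(wr), "deg",
            movement = m, phase_or_segment = ph),
        rec("aperture_adjustments", "phase",
            count_adjustments(ap, fs, cfg)$count, "count",
            movement = m, phase_or_segment = ph),
        rec("wrist_adjustments", "phase",
            count_adjustments(wr, fs, cfg)$count, "count",
            movement = m, phase_or_segment = ph)))
      if (!is.null(env)) {
        inph <- trial$emg$t >= w$start_s - 1e-9 & trial$emg$t <= w$end_s + 1e-9
        rows <- c(rows, list(
          rec("total_muscle_activity", "phase", sum(env[inph]), "a.u.",
              movement = m, phase_or_segment = ph)))
      }
      if (trial$task_id %in% simultaneity_tasks && ph %in% c("Reach", "Transport")) {
        insel <- trial$kinematics$t >= mw[1] - 1e-9 & trial$kinematics$t <= mw[2] + 1e-9
        rows <- c(rows, list(
          rec("simultaneity", "phase",
              simultaneous_wrist_shoulder(wrist[insel], shoulder[insel],
                                          trial$kinematics$t[insel],
                                          c(w$start_s, w$end_s), fs,
                                          thresholds, cfg), "%",
              movement = m, phase_or_segment = ph)))
      }
    }
    for (sgl in segment_labels) {
      w <- seg_segment(seg, m, sgl)
      rows <- c(rows, list(
        rec("peak_hand_velocity", "movement_segment",
            peak_hand_velocity(trial, cfg = mcfg, window = w), "mm/s",
            movement = m, phase_or_segment = sgl),
        rec("hand_distance", "movement_segment",
            hand_distance_travelled(trial, window = w), "mm",
            movement = m, phase_or_segment = sgl)))
    }
    wrg <- seg_segment(seg, m, "Reach-Grasp")
    selrg <- trial$kinematics$t >= wrg$start_s - 1e-9 &
      trial$kinematics$t <= wrg$end_s + 1e-9
    rows <- c(rows, list(
      rec("aperture_plateau", "movement_segment",
          grip_aperture_plateau(aperture[selrg], fs, thresholds, cfg), "s",
          movement = m, phase_or_segment = "Reach-Grasp")))
  }
  do.call(rbind, rows)
}

# Baseline-subtracted, channel-summed, low-passed activity envelope at the
# EMG rate; shared by total_muscle_activity and the trial pipeline.
activity_envelope <- function(femg, rest, cfg) {
  rect <- abs(femg$values[, emg_channels, drop = FALSE])
  norm <- sweep(rect, 2, rest$channel_means)
  if (cfg$clip_negative_activity) norm[norm < 0] <- 0
  lowpass_zero_phase(rowSums(norm), femg$fs, cfg$envelope_lowpass_hz)
}

#' Compute all metrics for one session (one participant, controller, task)
#'
#' Per-trial metrics for each trial plus the between-trial metrics:
#' task-level success rate (error-free trials over attempted) and per-
#' participant hand trajectory variability per movement and segment type
#' across trials.
#'
#' @param trials List of [trial_recording()]s of one participant x
#'   controller x task.
#' @param rest A [rest_reference()] or NULL.
#' @param segs Optional list of segmentations parallel to `trials`
#'   (defaults to automatic detection).
#' @param n_attempted Number of possible trial attempts for the success
#'   rate (defaults to `length(trials)`).
#' @inheritParams compute_trial_metrics
#' @return Metric-table data.frame.
#' @export
compute_session_metrics <- function(trials, rest = NULL, segs = NULL,
                                    n_attempted = length(trials),
                                    cfg = preprocess_config(),
                                    thresholds = threshold_set(),
                                    mcfg = metric_config()) {
  if (!length(trials)) stop_promet("too_few_trials", "no trials supplied")
  if (is.null(segs)) segs <- lapply(trials, segment_trial)
  per_trial <- Map(function(tr, sg) {
    compute_trial_metrics(tr, sg, rest, cfg, thresholds, mcfg)
  }, trials, segs)
  out <- do.call(rbind, per_trial)
  t1 <- trials[[1]]
  out <- rbind(out, metric_record(
    t1$participant_id, t1$controller_id, t1$task_id, "success_rate", "task",
    success_rate(sum(vapply(trials, `[[`, logical(1), "error_free")),
                 n_attempted), "%"))
  if (length(trials) >= 2L) {
    for (m in 1:3) {
      for (sgl in segment_labels) {
        trajs <- Map(function(tr, sg) {
          hand_positions(tr, seg_segment(sg, m, sgl))$xyz
        }, trials, segs)
        out <- rbind(out, metric_record(
          t1$participant_id, t1$controller_id, t1$task_id,
          "trajectory_variability", "movement_segment",
          hand_trajectory_variability(trajs, mcfg), "mm",
          movement = m, phase_or_segment = sgl))
      }
    }
  }
  out
}

#' Compute the metric table for a whole synthetic cohort
#'
#' @param cohort A `promet_cohort` from [generate_cohort()].
#' @param use_truth_segmentation Use the generator's threshold-consistent
#'   ground-truth boundaries instead of automatic detection (faster;
#'   useful to isolate metric behaviour from detection behaviour).
#' @param with_emg Include the total muscle activity metric.
#' @inheritParams compute_trial_metrics
#' @return Metric-table data.frame across all sessions.
#' @export
compute_cohort_metrics <- function(cohort, use_truth_segmentation = FALSE,
                                   with_emg = TRUE,
                                   cfg = preprocess_config(),
                                   thresholds = threshold_set(),
                                   mcfg = metric_config()) {
  stopifnot(inherits(cohort, "promet_cohort"))
  tabs <- lapply(cohort$sessions, function(s) {
    segs <- if (use_truth_segmentation) {
      lapply(s$truths, truth_segmentation)
    } else NULL
    compute_session_metrics(s$trials, rest = if (with_emg) s$rest else NULL,
                            segs = segs, n_attempted = s$n_attempted,
                            cfg = cfg, thresholds = thresholds, mcfg = mcfg)
  })
  do.call(rbind, tabs)
}
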