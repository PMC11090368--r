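#' Read and write trials, sessions and metric tables
#'
#' Canonical on-disk schema: per trial one kinematics CSV
#' (`time_s, hand_x_mm, hand_y_mm, hand_z_mm, aperture_mm, wrist_rot_deg,
#' shoulder_fe_deg, obj1_x_mm, obj1_y_mm, obj1_z_mm[, obj2..]`), one EMG CSV
#' (`time_s, emg_1..emg_8`), an optional motor CSV
#' (`time_s, hand_motor, wrist_motor`), plus a JSON session manifest naming
#' the files, identifiers, per-trial `error_free` flags, attempted/analyzed
#' trial counts and the rest-reference CSV (`channel, mean_rectified`).
#'
#' @param path Manifest path.
#' @return `read_manifest`: the parsed manifest (list with a `sessions`
#'   list).
#' @name trial_io
NULL

kin_csv_cols <- c("time_s", "hand_x_mm", "hand_y_mm", "hand_z_mm",
                  "aperture_mm", "wrist_rot_deg", "shoulder_fe_deg")

#' @rdname trial_io
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$sessions)) stop_promet("bad_manifest", "manifest has no sessions")
  j$base_dir <- dirname(normalizePath(path))
  j
}

#' Load one trial from a session manifest entry
#'
#' Reads the referenced CSV files, checks the schema and all container
#' invariants, and returns a validated [trial_recording()]. Distinct
#' conditions are signalled for a missing column (`promet_missing_column`),
#' non-monotonic time (`promet_nonmonotonic_time`), sampling-rate mismatch
#' (`promet_sampling_rate_mismatch`) and out-of-range EMG
#' (`promet_emg_out_of_range`).
#'
#' @param session One element of `read_manifest(path)$sessions`.
#' @param trial_index Which trial of the session to load.
#' @param base_dir Directory against which relative paths resolve.
#' @return A `promet_trial`.
#' @export
load_trial <- function(session, trial_index, base_dir = ".") {
  entry <- NULL
  for (e in session$trials) {
    if (e$trial_index == trial_index) entry <- e
  }
  if (is.null(entry)) {
    stop_promet("bad_manifest", "no trial %s in session", trial_index)
  }
  kin_df <- read_schema_csv(file.path(base_dir, entry$kinematics), kin_csv_cols)
  obj_cols <- grep("^obj[0-9]+_[xyz]_mm$", names(kin_df), value = TRUE)
  if (!length(obj_cols)) {
    stop_promet("missing_column", "kinematics CSV has no object columns")
  }
  fs_kin <- session$fs_kinematics %||% 120
  fs_emg <- session$fs_emg %||% 200
  kin_vals <- as.matrix(kin_df[kin_csv_cols[-1]])
  colnames(kin_vals) <- kin_channels
  kin <- promet_ts(kin_df$time_s, kin_vals, fs_kin)
  obj_vals <- as.matrix(kin_df[obj_cols])
  colnames(obj_vals) <- sub("_mm$", "", obj_cols)
  objects <- promet_ts(kin_df$time_s, obj_vals, fs_kin)
  emg_df <- read_schema_csv(file.path(base_dir, entry$emg),
                            c("time_s", emg_channels))
  emg <- promet_ts(emg_df$time_s, as.matrix(emg_df[emg_channels]), fs_emg)
  motor <- NULL
  if (!is.null(entry$motor)) {
    mo_df <- read_schema_csv(file.path(base_dir, entry$motor),
                             c("time_s", "hand_motor", "wrist_motor"))
    motor <- promet_ts(mo_df$time_s,
                       as.matrix(mo_df[c("hand_motor", "wrist_motor")]),
                       session$fs_motor %||% 50)
  }
  trial_recording(session$participant_id, session$controller_id,
                  session$task_id, entry$trial_index,
                  isTRUE(entry$error_free), kin, objects, emg, motor)
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop_promet("missing_file", "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_promet("missing_column", "%s lacks column(s): %s", basename(path),
                paste(miss, collapse = ", "))
  }
  df
}

#' @rdname trial_io
#' @param rest_path Rest-reference CSV path.
#' @export
read_rest_reference <- function(rest_path) {
  df <- read_schema_csv(rest_path, c("channel", "mean_rectified"))
  rest_reference(df$mean_rectified[order(df$channel)])
}

#' Write a generated cohort to disk in the manifest schema
#'
#' @param cohort A `promet_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest JSON.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- lapply(cohort$sessions, function(s) {
    tag <- sprintf("%s_%s_%s", s$participant_id, s$controller_id, s$task_id)
    rest_file <- sprintf("%s_rest.csv", tag)
    utils::write.csv(data.frame(channel = seq_len(8),
                                mean_rectified = s$rest$channel_means),
                     file.path(dir, rest_file), row.names = FALSE)
    entries <- lapply(s$trials, function(tr) {
      stem <- sprintf("%s_t%02d", tag, tr$trial_index)
      write_trial_csvs(tr, dir, stem)
    })
    list(participant_id = s$participant_id, controller_id = s$controller_id,
         task_id = s$task_id, fs_kinematics = 120, fs_emg = 200, fs_motor = 50,
         rest_reference = rest_file, n_attempted = s$n_attempted,
         n_analyzed = s$n_analyzed, trials = entries)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(sessions = sessions), path, auto_unbox = TRUE,
                       digits = NA)
  path
}

write_trial_csvs <- function(trial, dir, stem) {
  k <- trial$kinematics; o <- trial$objects
  kin_df <- data.frame(time_s = k$t)
  kin_df[kin_csv_cols[-1]] <- as.data.frame(k$values[, kin_channels])
  obj_cols <- paste0(colnames(o$values), "_mm")
  kin_df[obj_cols] <- as.data.frame(o$values)
  kin_file <- paste0(stem, "_kin.csv")
  utils::write.csv(kin_df, file.path(dir, kin_file), row.names = FALSE)
  emg_df <- data.frame(time_s = trial$emg$t)
  emg_df[emg_channels] <- as.data.frame(trial$emg$values)
  emg_file <- paste0(stem, "_emg.csv")
  utils::write.csv(emg_df, file.path(dir, emg_file), row.names = FALSE)
  entry <- list(trial_index = trial$trial_index, error_free = trial$error_free,
                kinematics = kin_file, emg = emg_file)
  if (!is.null(trial$motor)) {
    mo_df <- data.frame(time_s = trial$motor$t,
                        hand_motor = ts_channel(trial$motor, "hand_motor"),
                        wrist_motor = ts_channel(trial$motor, "wrist_motor"))
    entry$motor <- paste0(stem, "_motor.csv")
    utils::write.csv(mo_df, file.path(dir, entry$motor), row.names = FALSE)
  }
  entry
}

#' Write and read the metric table
#'
#' One [metric_record()] per row; `read_metrics(write_metrics(x)) == x`
#' field for field. Reading validates the analysis-level labels and names
#' the offending line on failure.
#'
#' @param records Metric-table data.frame.
#' @param path CSV path.
#' @export
write_metrics <- function(records, path) {
  validate_metric_table(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- read_schema_csv(path, c("participant_id", "controller_id", "task_id",
                                "metric", "level", "trial_index", "movement",
                                "phase_or_segment", "value", "units"))
  if (nrow(df)) {
    bad <- which(!df$level %in% metric_levels)
    if (length(bad)) {
      stop_promet("parse_error", "unknown level '%s' at line %d",
                  df$level[bad[1]], bad[1] + 1L)  # +1 for the header line
    }
    df$participant_id <- as.character(df$participant_id)
    df$controller_id <- as.character(df$controller_id)
    df$task_id <- as.character(df$task_id)
    df$metric <- as.character(df$metric)
    df$trial_index <- as.integer(df$trial_index)
    df$movement <- as.integer(df$movement)
    df$phase_or_segment <- as.character(df$phase_or_segment)
    df$phase_or_segment[is.na(df$phase_or_segment) | df$phase_or_segment == ""] <- NA
    df$units <- as.character(df$units)
    df$units[is.na(df$units)] <- ""
    validate_metric_table(df)
  } else {
    df$phase_or_segment <- as.character(df$phase_or_segment)
    for (col in c("participant_id", "controller_id", "task_id", "metric",
                  "level", "units")) df[[col]] <- as.character(df[[col]])
    df$trial_index <- as.integer(df$trial_index)
    df$movement <- as.integer(df$movement)
  }
  df
}
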