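#' Segmentation configuration
#'
#' Event-detection thresholds for splitting a trial into movements and
#' phases. Motion onsets/offsets are defined by speed crossing a fraction of
#' the relevant peak speed: `hand_speed_onset_frac` for the hand,
#' `object_speed_onset_frac` for the transported object (both default 0.05).
#' Speeds are moving-average smoothed over `speed_smooth_s` before
#' thresholding. Object-speed bouts separated by less than `min_bout_gap_s`
#' are merged, and hand-motion intervals shorter than `min_phase_s` are
#' ignored as blips. Phases shorter than `min_phase_s` after detection are
#' retained with a warning.
#'
#' @param hand_speed_onset_frac,object_speed_onset_frac Fractions in (0, 1).
#' @param min_phase_s Minimum phase duration in seconds.
#' @param speed_smooth_s Moving-average window (s) applied to speeds.
#' @param min_bout_gap_s Minimum gap (s) between distinct object bouts.
#' @return Object of class `promet_segcfg`.
#' @export
segmentation_config <- function(hand_speed_onset_frac = 0.05,
                                object_speed_onset_frac = 0.05,
                                min_phase_s = 0.05,
                                speed_smooth_s = 0.05,
                                min_bout_gap_s = 0.2) {
  if (hand_speed_onset_frac <= 0 || hand_speed_onset_frac >= 1 ||
      object_speed_onset_frac <= 0 || object_speed_onset_frac >= 1) {
    stop_promet("bad_config", "onset fractions must lie in (0, 1)")
  }
  if (min_phase_s < 0) stop_promet("bad_config", "min_phase_s must be >= 0")
  structure(list(hand_speed_onset_frac = hand_speed_onset_frac,
                 object_speed_onset_frac = object_speed_onset_frac,
                 min_phase_s = min_phase_s,
                 speed_smooth_s = speed_smooth_s,
                 min_bout_gap_s = min_bout_gap_s),
            class = "promet_segcfg")
}

phase_order <- c("Reach", "Grasp", "Transport", "Release", "Home")

# Smoothed 3D speed of a named x/y/z channel triple.
triple_speed <- function(ts, prefix, smooth_s) {
  v <- vapply(paste0(prefix, c("_x", "_y", "_z")),
              function(ch) time_derivative(ts_channel(ts, ch), ts$fs),
              numeric(length(ts$t)))
  sp <- sqrt(rowSums(v^2))
  moving_average(sp, smooth_samples(smooth_s, ts$fs))
}

hand_speed <- function(trial, cfg) {
  triple_speed(trial$kinematics, "hand", cfg$speed_smooth_s)
}

object_prefixes <- function(trial) {
  nm <- colnames(trial$objects$values)
  unique(sub("_[xyz]$", "", nm[grepl("_[xyz]$", nm)]))
}

# Composite object speed: per-sample max over all tracked objects.
object_speed <- function(trial, cfg) {
  sp <- vapply(object_prefixes(trial),
               function(p) triple_speed(trial$objects, p, cfg$speed_smooth_s),
               numeric(length(trial$objects$t)))
  if (is.null(dim(sp))) sp else apply(sp, 1, max)
}

# Runs of TRUE as an index-interval matrix (cols: from, to).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(from = starts[r$values], to = ends[r$values])
}

merge_close_runs <- function(runs, t, gap_s) {
  if (nrow(runs) < 2L) return(runs)
  keep <- list(runs[1L, ])
  for (i in 2:nrow(runs)) {
    last <- keep[[length(keep)]]
    if (t[runs[i, "from"]] - t[last["to"]] < gap_s) {
      last["to"] <- runs[i, "to"]
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1L]] <- runs[i, ]
  }
  do.call(rbind, keep)
}

#' Split a trial into its three object-transport movements
#'
#' Detects object-transport bouts (composite object speed above
#' `object_speed_onset_frac` of its trial peak) and, for each bout, extends
#' the movement from the onset of the hand motion preceding the bout (the
#' reach) to the offset of the hand motion following it (the return toward
#' home). Exactly three bouts must be found.
#'
#' @param trial A [trial_recording()].
#' @param cfg A [segmentation_config()].
#' @return data.frame with columns `movement`, `start_s`, `end_s`.
#' @export
segment_movements <- function(trial, cfg = segmentation_config()) {
  t <- trial$kinematics$t
  hs <- hand_speed(trial, cfg)
  os <- object_speed(trial, cfg)
  if (max(os) <= 0) stop_promet("bad_bout_count", "expected 3 object-transport bouts, found 0")
  bouts <- true_runs(os > cfg$object_speed_onset_frac * max(os))
  bouts <- merge_close_runs(bouts, t, cfg$min_bout_gap_s)
  if (nrow(bouts) != 3L) {
    stop_promet("bad_bout_count", "expected 3 object-transport bouts, found %d",
                nrow(bouts))
  }
  thr <- cfg$hand_speed_onset_frac * max(hs)
  moving <- true_runs(hs >= thr)
  moving <- moving[t[moving[, "to"]] - t[moving[, "from"]] >= cfg$min_phase_s, ,
                   drop = FALSE]
  win <- lapply(seq_len(3L), function(k) {
    mid <- (bouts[k, "from"] + bouts[k, "to"]) %/% 2L
    itr <- which(moving[, "from"] <= mid & moving[, "to"] >= mid)
    if (length(itr) != 1L) {
      stop_promet("no_hand_motion", "hand not moving during transport bout %d", k)
    }
    if (itr == 1L || itr == nrow(moving)) {
      stop_promet("no_hand_motion",
                  "no distinct reach/return hand motion around bout %d", k)
    }
    c(from = unname(moving[itr - 1L, "from"]),
      to = unname(moving[itr + 1L, "to"]))
  })
  out <- data.frame(movement = 1:3,
                    start_s = t[vapply(win, `[[`, integer(1), "from")],
                    end_s = t[vapply(win, `[[`, integer(1), "to")])
  if (any(diff(out$start_s) <= 0) || any(out$end_s[-3] > out$start_s[-1])) {
    stop_promet("bad_bout_count", "detected movements overlap or are unordered")
  }
  out
}

#' Split one movement into its five phases
#'
#' Within a movement window: Transport spans the samples where composite
#' object speed exceeds `object_speed_onset_frac` of its in-window peak;
#' Grasp runs from the hand's arrival at the object (hand speed falling
#' below `hand_speed_onset_frac` of its in-window peak) to Transport onset;
#' Reach from the movement start to Grasp onset; Release from Transport end
#' to the hand-retreat onset; Home covers the remainder. Boundaries snap to
#' sample timestamps. Phases shorter than `min_phase_s` are kept with a
#' warning.
#'
#' @param trial A [trial_recording()].
#' @param movement Either one row of [segment_movements()] output or a
#'   numeric `c(start_s, end_s)`.
#' @param cfg A [segmentation_config()].
#' @return data.frame with columns `label`, `start_s`, `end_s` in the fixed
#'   order Reach, Grasp, Transport, Release, Home.
#' @export
segment_phases <- function(trial, movement, cfg = segmentation_config()) {
  if (is.data.frame(movement)) movement <- c(movement$start_s[1], movement$end_s[1])
  t_all <- trial$kinematics$t
  sel <- which(t_all >= movement[1] - 1e-9 & t_all <= movement[2] + 1e-9)
  if (length(sel) < 5L) stop_promet("too_few_samples", "movement window too short")
  t <- t_all[sel]
  hs <- hand_speed(trial, cfg)[sel]
  os <- object_speed(trial, cfg)[sel]
  if (max(os) <= 0) stop_promet("no_transport", "object stationary in movement window")
  above <- which(os > cfg$object_speed_onset_frac * max(os))
  i_ts <- above[1L]; i_te <- above[length(above)]
  thr <- cfg$hand_speed_onset_frac * max(hs)
  below_before <- which(hs[seq_len(i_ts - 1L)] < thr)
  # require a genuine arrival: a sub-threshold sample preceded by motion
  below_before <- below_before[below_before > 1L & hs[below_before - 1L] >= thr]
  if (!length(below_before)) {
    stop_promet("undetectable_grasp",
                "hand never decelerates below threshold before transport")
  }
  i_gs <- below_before[length(below_before)]
  # hand settles below threshold after releasing, then rises to return home
  settled <- which(hs < thr)
  settled <- settled[settled > i_te]
  if (length(settled)) {
    retreat <- which(hs >= thr)
    retreat <- retreat[retreat > settled[1L]]
    i_hs <- if (length(retreat)) retreat[1L] else length(t)
  } else i_hs <- length(t)
  idx <- c(1L, i_gs, i_ts, i_te, i_hs, length(t))
  if (is.unsorted(idx)) {
    stop_promet("undetectable_grasp", "phase boundaries out of order")
  }
  out <- data.frame(label = phase_order,
                    start_s = t[idx[1:5]], end_s = t[idx[2:6]])
  short <- out$end_s - out$start_s < cfg$min_phase_s
  if (any(short)) {
    warn_promet("short_phase", "phase(s) shorter than %g s: %s", cfg$min_phase_s,
                paste(out$label[short], collapse = ", "))
  }
  out
}

#' Full segmentation of a trial
#'
#' Runs [segment_movements()] then [segment_phases()] per movement and
#' derives the Reach-Grasp and Transport-Release movement segments.
#'
#' @param trial A [trial_recording()].
#' @param cfg A [segmentation_config()].
#' @return Object of class `promet_seg`: a list with one entry per movement,
#'   each holding `start_s`, `end_s`, `phases` (5-row data.frame) and
#'   `segments` (2-row data.frame).
#' @export
segment_trial <- function(trial, cfg = segmentation_config()) {
  mv <- segment_movements(trial, cfg)
  movements <- lapply(seq_len(3L), function(k) {
    ph <- segment_phases(trial, mv[k, ], cfg)
    list(start_s = mv$start_s[k], end_s = mv$end_s[k], phases = ph,
         segments = derive_segments(ph))
  })
  new_segmentation(movements, span = range(trial$kinematics$t))
}

derive_segments <- function(ph) {
  data.frame(label = segment_labels,
             start_s = c(ph$start_s[ph$label == "Reach"],
                         ph$start_s[ph$label == "Transport"]),
             end_s = c(ph$end_s[ph$label == "Grasp"],
                       ph$end_s[ph$label == "Release"]))
}

new_segmentation <- function(movements, span = NULL, sample_dt = 1 / 120) {
  x <- structure(list(movements = movements, span = span,
                      sample_dt = sample_dt), class = "promet_seg")
  validate_segmentation(x)
  x
}

#' @rdname segment_trial
#' @param x A `promet_seg` to validate: exactly 3 movements, phases in fixed
#'   order and contiguous within one sample period, movements ordered and
#'   non-overlapping, all bounds inside the trial span.
#' @export
validate_segmentation <- function(x) {
  stopifnot(inherits(x, "promet_seg"))
  if (length(x$movements) != 3L) {
    stop_promet("bad_segmentation", "need exactly 3 movements, have %d",
                length(x$movements))
  }
  tol <- x$sample_dt + 1e-9
  prev_end <- -Inf
  for (m in x$movements) {
    ph <- m$phases
    if (!identical(ph$label, phase_order)) {
      stop_promet("bad_segmentation", "phases must be %s in order",
                  paste(phase_order, collapse = ", "))
    }
    if (any(ph$end_s < ph$start_s)) {
      stop_promet("bad_segmentation", "phase with end before start")
    }
    if (any(abs(ph$start_s[-1] - ph$end_s[-5]) > tol)) {
      stop_promet("bad_segmentation", "phases not contiguous within one sample")
    }
    if (ph$start_s[1] < prev_end - 1e-9) {
      stop_promet("bad_segmentation", "movements overlap")
    }
    if (!is.null(x$span) &&
        (ph$start_s[1] < x$span[1] - 1e-9 || ph$end_s[5] > x$span[2] + 1e-9)) {
      stop_promet("bad_segmentation", "bounds outside trial span")
    }
    prev_end <- ph$end_s[5]
  }
  invisible(x)
}

#' @export
print.promet_seg <- function(x, ...) {
  cat("<promet_seg> 3 movements\n")
  for (k in 1:3) {
    m <- x$movements[[k]]
    d <- m$phases$end_s - m$phases$start_s
    cat(sprintf("  movement %d [%.3f, %.3f] s  phases: %s\n", k,
                m$start_s, m$end_s,
                paste(sprintf("%s %.2f", m$phases$label, d), collapse = ", ")))
  }
  invisible(x)
}

# Accessors -----------------------------------------------------------------

seg_phase <- function(seg, movement, label) {
  ph <- seg$movements[[movement]]$phases
  ph[ph$label == label, c("start_s", "end_s")]
}

seg_segment <- function(seg, movement, label) {
  sg <- seg$movements[[movement]]$segments
  sg[sg$label == label, c("start_s", "end_s")]
}

#' Read or write segmentation boundaries as JSON
#'
#' The events file lists 3 movements, each with 5 labelled phases; reading
#' validates contiguity, ordering and span, and bypasses automatic
#' detection.
#'
#' @param path File path.
#' @return `load_segmentation`: a validated `promet_seg`.
#' @export
load_segmentation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$movements) || length(j$movements) == 0) {
    stop_promet("bad_segmentation", "events file lists no movements")
  }
  movements <- lapply(j$movements, function(m) {
    if (is.null(m$phases)) {
      stop_promet("bad_segmentation", "movement entry lacks phases")
    }
    ph <- do.call(rbind, lapply(m$phases, function(p) {
      data.frame(label = as.character(p$label),
                 start_s = as.numeric(p$start_s),
                 end_s = as.numeric(p$end_s), stringsAsFactors = FALSE)
    }))
    ph <- ph[match(phase_order, ph$label), ]
    if (any(is.na(ph$label))) {
      stop_promet("bad_segmentation", "each movement needs the 5 named phases")
    }
    rownames(ph) <- NULL
    list(start_s = ph$start_s[1], end_s = ph$end_s[5], phases = ph,
         segments = derive_segments(ph))
  })
  sample_dt <- j$sample_dt %||% (1 / 120)
  new_segmentation(movements, span = unlist(j$span), sample_dt = sample_dt)
}

#' @rdname load_segmentation
#' @param seg A `promet_seg`.
#' @export
write_segmentation <- function(seg, path) {
  validate_segmentation(seg)
  j <- list(sample_dt = seg$sample_dt, span = seg$span,
            movements = lapply(seg$movements, function(m) {
              list(phases = m$phases)
            }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
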