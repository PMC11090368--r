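#' Synthetic cohort configuration
#'
#' Parameters of a two-arm study emulation: `n_participants` participants
#' each perform `trials_per_task` trials of each task under two controllers.
#' One arm (named by `degraded_controller`) can receive a per-movement
#' degradation schedule that emulates the limb position effect: the
#' schedule's vectors give, for movements 1-3, the mean number of extra
#' adjustment reversals injected into the Grasp phase (Poisson across
#' trials), extra plateau hold, hand-path noise RMS, wrist wiggle scale,
#' reduction of the wrist-shoulder simultaneity overlap, and EMG effort
#' scale. Medians and spreads thus grow with movement number in the
#' degraded arm, as the limb position effect does with limb height.
#'
#' @param n_participants Number of participants.
#' @param tasks Subset of `c("PASTA", "RCRT_UP", "RCRT_DOWN")`.
#' @param trials_per_task Trials per participant, task and controller.
#' @param seed Master integer seed.
#' @param controllers Two controller labels.
#' @param degraded_controller Label of the arm receiving the degradation
#'   schedule, or `NULL` for none.
#' @param degradation List of per-movement length-3 vectors (see above).
#' @param duration_jitter Lognormal sd of per-trial phase duration scaling.
#' @param error_rate Per-arm probability that a trial is not error-free
#'   (length 2, clean/degraded order follows `controllers`).
#' @return Object of class `promet_cohortcfg`.
#' @export
synthetic_cohort_config <- function(n_participants = 8,
                                    tasks = c("PASTA", "RCRT_UP", "RCRT_DOWN"),
                                    trials_per_task = 10, seed = 1L,
                                    controllers = c("CTRL_A", "CTRL_B"),
                                    degraded_controller = "CTRL_B",
                                    degradation = default_degradation(),
                                    duration_jitter = 0.08,
                                    error_rate = c(0.05, 0.1)) {
  if (n_participants < 1 || trials_per_task < 1) {
    stop_promet("bad_config", "counts must be positive")
  }
  tasks <- match.arg(tasks, c("PASTA", "RCRT_UP", "RCRT_DOWN"),
                     several.ok = TRUE)
  if (length(controllers) != 2L) {
    stop_promet("bad_config", "exactly two controllers expected")
  }
  if (!is.null(degraded_controller) && !degraded_controller %in% controllers) {
    stop_promet("bad_config", "degraded_controller must be one of controllers")
  }
  deg <- utils::modifyList(default_degradation(), degradation)
  if (any(vapply(deg, length, integer(1)) != 3L)) {
    stop_promet("bad_config", "degradation vectors must have length 3")
  }
  if (any(deg$trajectory_noise_mm < 0) || any(deg$plateau_extension_s < 0) ||
      any(deg$extra_adjustments_mean < 0)) {
    stop_promet("bad_config", "noise, extension and adjustment means must be >= 0")
  }
  structure(list(n_participants = as.integer(n_participants), tasks = tasks,
                 trials_per_task = as.integer(trials_per_task),
                 seed = as.integer(seed), controllers = controllers,
                 degraded_controller = degraded_controller,
                 degradation = deg, duration_jitter = duration_jitter,
                 error_rate = error_rate),
            class = "promet_cohortcfg")
}

#' @rdname synthetic_cohort_config
#' @export
default_degradation <- function() {
  list(extra_adjustments_mean = c(0, 0.5, 4),
       plateau_extension_s = c(0, 0.05, 0.3),
       trajectory_noise_mm = c(0, 1, 2),
       wrist_excursion_scale = c(1, 1.2, 2),
       sim_overlap_drop = c(0, 0.1, 0.4),
       emg_effort_scale = c(1, 1.1, 1.6))
}

no_degradation <- function() {
  list(extra_adjustments_mean = c(0, 0, 0), plateau_extension_s = c(0, 0, 0),
       trajectory_noise_mm = c(0, 0, 0), wrist_excursion_scale = c(1, 1, 1),
       sim_overlap_drop = c(0, 0, 0), emg_effort_scale = c(1, 1, 1))
}

#' Generate a synthetic two-arm cohort with ground truth
#'
#' Draws per-participant skill factors and per-trial seeds from the master
#' seed, generates every trial with [generate_trial()], and builds one rest
#' EMG reference per participant-controller session. With `dir` set, all
#' trials are written in the package's CSV + JSON manifest schema via
#' [write_cohort()].
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param dir Optional output directory.
#' @return Object of class `promet_cohort`: list of sessions, each with
#'   identifiers, `trials`, `truths`, `rest`, `n_attempted`, `n_analyzed`;
#'   plus the `cfg`. When `dir` is set, `manifest_path` is added.
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "promet_cohortcfg"))
  set.seed(cfg$seed)
  participants <- sprintf("P%02d", seq_len(cfg$n_participants))
  # per-participant multipliers: adjustment propensity and tempo
  adj_factor <- exp(stats::rnorm(cfg$n_participants, 0, 0.4))
  tempo <- exp(stats::rnorm(cfg$n_participants, 0, cfg$duration_jitter))
  sessions <- list()
  for (ip in seq_along(participants)) {
    for (ic in seq_along(cfg$controllers)) {
      ctrl <- cfg$controllers[ic]
      degraded <- !is.null(cfg$degraded_controller) &&
        ctrl == cfg$degraded_controller
      deg <- if (degraded) cfg$degradation else no_degradation()
      rest_emg <- synth_rest_emg(5, 200)
      rest <- rest_reference_from_emg(rest_emg)
      for (task in cfg$tasks) {
        trials <- vector("list", cfg$trials_per_task)
        truths <- vector("list", cfg$trials_per_task)
        for (tr in seq_len(cfg$trials_per_task)) {
          mv <- lapply(1:3, function(m) {
            K_ap <- stats::rpois(1, deg$extra_adjustments_mean[m] * adj_factor[ip])
            K_wr <- stats::rpois(1, deg$extra_adjustments_mean[m] * adj_factor[ip])
            jit <- exp(stats::rnorm(1, 0, cfg$duration_jitter)) * tempo[ip]
            movement_params(
              reach_s = 0.8 * jit, grasp_s = 0.5 * jit,
              transport_s = 1.2 * jit, release_s = 0.4 * jit,
              home_s = 0.6 * jit,
              extra_ap_adj = c(Grasp = K_ap),
              extra_wr_adj = c(Grasp = K_wr),
              plateau_extension_s = deg$plateau_extension_s[m],
              trajectory_noise_mm = deg$trajectory_noise_mm[m],
              wrist_excursion_scale = deg$wrist_excursion_scale[m],
              sim_overlap_frac = max(0.1, 0.6 - deg$sim_overlap_drop[m]),
              emg_effort_scale = deg$emg_effort_scale[m])
          })
          err_p <- cfg$error_rate[if (degraded) 2L else 1L]
          efree <- stats::runif(1) > err_p
          trial_seed <- sample.int(.Machine$integer.max - 1L, 1L)
          g <- generate_trial(task, mv, seed = trial_seed,
                              participant_id = participants[ip],
                              controller_id = ctrl, trial_index = tr,
                              error_free = efree)
          trials[[tr]] <- g$trial
          truths[[tr]] <- g$truth
        }
        sessions[[length(sessions) + 1L]] <- list(
          participant_id = participants[ip], controller_id = ctrl,
          task_id = task, trials = trials, truths = truths, rest = rest,
          n_attempted = cfg$trials_per_task,
          n_analyzed = sum(vapply(trials, `[[`, logical(1), "error_free")))
      }
    }
  }
  out <- structure(list(sessions = sessions, cfg = cfg),
                   class = "promet_cohort")
  if (!is.null(dir)) out$manifest_path <- write_cohort(out, dir)
  out
}

synth_rest_emg <- function(dur_s, fs) {
  t <- seq(0, dur_s, by = 1 / fs)
  vals <- matrix(stats::rnorm(length(t) * 8, 0, 0.02), ncol = 8,
                 dimnames = list(NULL, emg_channels))
  promet_ts(t, pmin(pmax(vals, -1), 1), fs)
}

#' @export
print.promet_cohort <- function(x, ...) {
  cat(sprintf("<promet_cohort> %d sessions (%d participants x %d controllers x %d tasks), %d trials/task\n",
              length(x$sessions), x$cfg$n_participants, 2L,
              length(x$cfg$tasks), x$cfg$trials_per_task))
  invisible(x)
}
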