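# Independent brute-force oracles used by the equivalence tests. These
# deliberately use explicit loops and literal condition tables rather than
# the package's vectorized implementations.

# Enumerate adjustment transitions of an identically smoothed velocity by
# walking the sign sequence one sample at a time.
oracle_count_adjustments <- function(x, fs = 120, cfg = preprocess_config()) {
  v <- time_derivative(x, fs)
  v <- moving_average(v, promet:::smooth_samples(cfg$smooth_window_s, fs))
  db <- cfg$deadband_frac * max(abs(v))
  s <- integer(length(v))
  for (i in seq_along(v)) {
    s[i] <- if (abs(v[i]) <= db) 0L else if (v[i] > 0) 1L else -1L
  }
  count <- 0L
  for (i in 2:length(s)) {
    a <- s[i - 1]; b <- s[i]
    if (a == 0 && b == 1) count <- count + 1L
    else if (a == 0 && b == -1) count <- count + 1L
    else if (a == -1 && b == 1) count <- count + 1L
    else if (a == 1 && b == -1) count <- count + 1L
  }
  count
}

# Literal evaluation of the identification rule tables.
oracle_apply_rule <- function(med, iqr, rule_name) {
  if (rule_name == "PastaReachGrasp") {
    med[1] < 90 && med[2] < 75 && abs(med[3] - 100) < 1e-9 &&
      iqr[2] < 55 && abs(iqr[3] - 100) < 1e-9
  } else if (rule_name == "PastaTransportRelease") {
    abs(med[2] - 100) < 1e-9 && med[3] < 85 && abs(iqr[2] - 100) < 1e-9
  } else if (rule_name == "RCRT") {
    med[1] < 55 && med[2] < 85 && abs(med[3] - 100) < 1e-9 &&
      iqr[1] < 25 && iqr[3] > 80
  } else stop("unknown rule")
}

# Direct Friedman rank formula (no ties expected in the random tables).
oracle_friedman <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) R[i, ] <- rank(x[i, ])
  (12 / (n * k * (k + 1))) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

# Random rescaled stats object: percentages with the maximum pinned at 100
# and occasional exact ties, mimicking rescale_movement_stats output.
random_rescaled_stats <- function() {
  mk <- function() {
    v <- runif(3, 0, 100)
    v[sample(3, 1)] <- 100
    if (runif(1) < 0.2) v[sample(3, 1)] <- 100  # ties on the maximum
    if (runif(1) < 0.3) v <- round(v, 0)        # hit thresholds exactly
    v
  }
  st <- rescale_movement_stats(c(1, 1, 1), c(1, 1, 1))
  st$rescaled_medians <- mk()
  st$rescaled_iqrs <- mk()
  st
}

# Shared generated-cohort cache so acceptance blocks reuse one cohort.
.promet_test_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, maker) {
  if (is.null(.promet_test_cache[[key]])) .promet_test_cache[[key]] <- maker()
  .promet_test_cache[[key]]
}

# Lean phase-level metric table (control-characteristics only) computed
# against the generator's threshold-consistent boundaries.
lean_control_metrics <- function(cohort) {
  rows <- list()
  for (s in cohort$sessions) {
    for (i in seq_along(s$trials)) {
      tr <- s$trials[[i]]
      seg <- truth_segmentation(s$truths[[i]])
      t <- tr$kinematics$t
      ap <- ts_channel(tr$kinematics, "aperture")
      wr <- ts_channel(tr$kinematics, "wrist_rot")
      sh <- ts_channel(tr$kinematics, "shoulder_fe")
      for (m in 1:3) {
        msel <- t >= seg$movements[[m]]$start_s & t <= seg$movements[[m]]$end_s
        for (ph in c("Reach", "Grasp", "Transport", "Release")) {
          w <- seg$movements[[m]]$phases
          w <- w[w$label == ph, ]
          sel <- t >= w$start_s - 1e-9 & t <= w$end_s + 1e-9
          base <- data.frame(participant_id = tr$participant_id,
                             controller_id = tr$controller_id,
                             task_id = tr$task_id, level = "phase",
                             trial_index = tr$trial_index, movement = m,
                             phase_or_segment = ph, units = "",
                             stringsAsFactors = FALSE)
          add <- function(metric, value) {
            cbind(base, data.frame(metric = metric, value = value))
          }
          rows[[length(rows) + 1L]] <- add("aperture_adjustments",
                                           count_adjustments(ap[sel])$count)
          rows[[length(rows) + 1L]] <- add("wrist_adjustments",
                                           count_adjustments(wr[sel])$count)
          rows[[length(rows) + 1L]] <- add("aperture_excursion",
                                           total_excursion(ap[sel]))
          rows[[length(rows) + 1L]] <- add("wrist_excursion",
                                           total_excursion(wr[sel]))
          if (tr$task_id != "PASTA" && ph %in% c("Reach", "Transport")) {
            rows[[length(rows) + 1L]] <- add("simultaneity",
              simultaneous_wrist_shoulder(wr[msel], sh[msel], t[msel],
                                          c(w$start_s, w$end_s)))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[c("participant_id", "controller_id", "task_id", "metric", "level",
        "trial_index", "movement", "phase_or_segment", "value", "units")]
}

# Constructed two-controller phase-level table for the statistics tests.
make_phase_table <- function(n = 8, shift = 0, sd = 1, seed = 1,
                             phases = c("Reach", "Grasp", "Transport", "Release")) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(
      data.frame(participant_id = sprintf("P%d", i), controller_id = "A",
                 task_id = "PASTA", metric = "m", level = "phase",
                 trial_index = 1L, movement = 1L, phase_or_segment = phases,
                 value = rnorm(length(phases), 10, sd), units = "",
                 stringsAsFactors = FALSE),
      data.frame(participant_id = sprintf("P%d", i), controller_id = "B",
                 task_id = "PASTA", metric = "m", level = "phase",
                 trial_index = 1L, movement = 1L, phase_or_segment = phases,
                 value = rnorm(length(phases), 10 + shift, sd), units = "",
                 stringsAsFactors = FALSE))
  }))
}
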