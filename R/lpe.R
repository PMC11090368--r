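#' Limb-position-effect identification rules
#'
#' Rule tables applied to across-participant movement statistics after
#' rescaling. Each rule row lists median and IQR conditions per movement
#' (values in percent of the maximum across the three movements); a
#' positive identification requires every condition of the rule to hold.
#' Blank cells impose no condition. The three built-in rules are:
#'
#' * `PastaReachGrasp` — M1 median < 90, M2 median < 75, M3 median = 100,
#'   M2 IQR < 55, M3 IQR = 100;
#' * `PastaTransportRelease` — M2 median = 100, M3 median < 85, M2 IQR = 100;
#' * `RCRT` — M1 median < 55, M2 median < 85, M3 median = 100,
#'   M1 IQR < 25, M3 IQR > 80.
#'
#' @return Named list of rule objects (class `promet_lperule`), each with a
#'   `conditions` data.frame (`stat`, `movement`, `op`, `threshold`).
#' @export
lpe_rules <- function() {
  mk <- function(name, conds) {
    structure(list(name = name, conditions = conds), class = "promet_lperule")
  }
  cond <- function(stat, movement, op, threshold) {
    data.frame(stat = stat, movement = movement, op = op,
               threshold = threshold, stringsAsFactors = FALSE)
  }
  list(
    PastaReachGrasp = mk("PastaReachGrasp", rbind(
      cond("median", 1, "<", 90), cond("median", 2, "<", 75),
      cond("median", 3, "=", 100),
      cond("iqr", 2, "<", 55), cond("iqr", 3, "=", 100))),
    PastaTransportRelease = mk("PastaTransportRelease", rbind(
      cond("median", 2, "=", 100), cond("median", 3, "<", 85),
      cond("iqr", 2, "=", 100))),
    RCRT = mk("RCRT", rbind(
      cond("median", 1, "<", 55), cond("median", 2, "<", 85),
      cond("median", 3, "=", 100),
      cond("iqr", 1, "<", 25), cond("iqr", 3, ">", 80)))
  )
}

#' Rescale across-participant movement statistics to percent of maximum
#'
#' The three per-movement medians become percentages of the largest of the
#' three; the IQRs likewise, independently. When all three medians (or all
#' three IQRs) are zero, the statistic is marked not evaluable and no rule
#' can flag it.
#'
#' @param medians,iqrs Numeric length-3 vectors (movements 1-3).
#' @param metric,task,phase Optional labels carried along.
#' @return Object of class `promet_movstats` with `medians`, `iqrs`,
#'   `rescaled_medians`, `rescaled_iqrs`, `evaluable`.
#' @export
rescale_movement_stats <- function(medians, iqrs, metric = "", task = "",
                                   phase = "") {
  stopifnot(length(medians) == 3L, length(iqrs) == 3L)
  if (any(!is.finite(c(medians, iqrs))) || any(c(medians, iqrs) < 0)) {
    stop_promet("bad_stats", "medians and IQRs must be finite and >= 0")
  }
  med_ok <- max(medians) > 0
  iqr_ok <- max(iqrs) > 0
  structure(list(
    metric = metric, task = task, phase = phase,
    medians = medians, iqrs = iqrs,
    rescaled_medians = if (med_ok) 100 * medians / max(medians) else rep(NA_real_, 3),
    rescaled_iqrs = if (iqr_ok) 100 * iqrs / max(iqrs) else rep(NA_real_, 3),
    evaluable = med_ok && iqr_ok, inverted = FALSE
  ), class = "promet_movstats")
}

#' Invert rescaled medians for larger-is-better metrics
#'
#' For metrics where larger values indicate better control (the
#' simultaneity metric), each rescaled median is subtracted from 100% so it
#' represents the share of the phase in which simultaneous movement did
#' *not* occur, then re-rescaled to percent of the new maximum so the
#' equality-with-100% rule conditions stay applicable. IQRs are not
#' inverted. If the inverted medians have no real contrast — the largest
#' deviation from the best movement is below `min_contrast` percentage
#' points — the statistic is marked not evaluable: re-rescaling would
#' otherwise blow sampling noise up to the full 0-100 range and let rules
#' fire on homogeneous data.
#'
#' @param stats A `promet_movstats`.
#' @param min_contrast Minimum spread (percentage points, pre-rescale) the
#'   inverted medians must show to stay evaluable.
#' @return The modified `promet_movstats` with `inverted = TRUE`.
#' @export
invert_larger_is_better <- function(stats, min_contrast = 5) {
  stopifnot(inherits(stats, "promet_movstats"))
  if (!stats$evaluable) {
    stats$inverted <- TRUE
    return(stats)
  }
  flipped <- 100 - stats$rescaled_medians
  if (max(flipped) < min_contrast) {
    stats$rescaled_medians <- rep(NA_real_, 3)
    stats$evaluable <- FALSE
  } else {
    stats$rescaled_medians <- 100 * flipped / max(flipped)
  }
  stats$inverted <- TRUE
  stats
}

#' Apply one identification rule to rescaled movement statistics
#'
#' Evaluates every condition of the rule against the rescaled medians and
#' IQRs; the finding is flagged only when all conditions hold. Equality
#' with 100% is tested to 1e-9 absolute (the maximum is exactly 100 by
#' construction; ties mean several movements read 100 and all satisfy the
#' equality).
#'
#' @param stats A `promet_movstats` from [rescale_movement_stats()] (after
#'   [invert_larger_is_better()] where applicable).
#' @param rule One element of [lpe_rules()].
#' @return Object of class `promet_lpefinding`: `flagged`,
#'   `condition_results`, plus labels.
#' @export
apply_rule <- function(stats, rule) {
  stopifnot(inherits(stats, "promet_movstats"), inherits(rule, "promet_lperule"))
  conds <- rule$conditions
  if (!stats$evaluable) {
    res <- rep(NA, nrow(conds))
    return(structure(list(metric = stats$metric, task = stats$task,
                          phase = stats$phase, rule = rule$name,
                          flagged = FALSE, condition_results = res,
                          reason = "not evaluable (degenerate statistics)",
                          inverted = stats$inverted, stats = stats),
                     class = "promet_lpefinding"))
  }
  vals <- ifelse(conds$stat == "median",
                 stats$rescaled_medians[conds$movement],
                 stats$rescaled_iqrs[conds$movement])
  res <- mapply(function(v, op, thr) {
    switch(op,
           "<" = v < thr,
           ">" = v > thr,
           "=" = abs(v - thr) < 1e-9,
           stop_promet("bad_rule", "unknown comparator '%s'", op))
  }, vals, conds$op, conds$threshold)
  structure(list(metric = stats$metric, task = stats$task,
                 phase = stats$phase, rule = rule$name,
                 flagged = all(res), condition_results = unname(res),
                 reason = NULL, inverted = stats$inverted, stats = stats),
            class = "promet_lpefinding")
}

#' @export
print.promet_lpefinding <- function(x, ...) {
  cat(sprintf("<promet_lpefinding> %s %s %s [%s]: %s\n", x$task, x$phase,
              x$metric, x$rule,
              if (x$flagged) "LIMB POSITION EFFECT" else "not flagged"))
  invisible(x)
}

# Which rules apply to a task/phase. Pasta uses two rule options; the
# default restricts each option to its named phases (pasta_both_everywhere
# applies both options to every phase instead).
rules_for <- function(task, phase, pasta_both_everywhere = FALSE) {
  r <- lpe_rules()
  if (task == "PASTA") {
    if (pasta_both_everywhere) {
      r[c("PastaReachGrasp", "PastaTransportRelease")]
    } else if (phase %in% c("Reach", "Grasp")) {
      r["PastaReachGrasp"]
    } else {
      r["PastaTransportRelease"]
    }
  } else {
    r["RCRT"]
  }
}

# Metrics where larger values indicate better control.
larger_is_better_metrics <- function() "simultaneity"

#' Identify limb-position-effect instances across a metric table
#'
#' For every controller x task x phase x control-characteristics metric in
#' the table: per-participant phase-level values are averaged across trials
#' per movement, across-participant medians and IQRs (Q3 - Q1, linear
#' interpolation quantiles) are taken per movement, rescaled to percent of
#' maximum (inverting larger-is-better metrics), and the applicable rules
#' evaluated. For the pasta task a flag from either rule option counts.
#'
#' @param metrics Metric-table data.frame with phase-level, per-movement
#'   rows for at least 2 participants.
#' @param metric_names Control-characteristics metrics to examine.
#' @param pasta_both_everywhere Apply both pasta rule options to all phases.
#' @return data.frame of findings (one row per controller x task x phase x
#'   metric x rule) with attribute `"findings"` holding the full objects.
#' @export
identify_lpe <- function(metrics,
                         metric_names = c("aperture_excursion",
                                          "wrist_excursion",
                                          "aperture_adjustments",
                                          "wrist_adjustments",
                                          "simultaneity",
                                          "total_muscle_activity"),
                         pasta_both_everywhere = FALSE) {
  validate_metric_table(metrics)
  ph <- metrics[metrics$level == "phase" & metrics$metric %in% metric_names, ]
  if (!nrow(ph) || all(is.na(ph$movement))) {
    stop_promet("missing_level", "table has no phase-level per-movement rows")
  }
  if (length(unique(ph$participant_id)) < 2L) {
    stop_promet("too_few_participants", "need at least 2 participants")
  }
  findings <- list()
  rows <- list()
  for (ctrl in unique(ph$controller_id)) {
    for (task in unique(ph$task_id[ph$controller_id == ctrl])) {
      sub <- ph[ph$controller_id == ctrl & ph$task_id == task, ]
      for (met in intersect(metric_names, unique(sub$metric))) {
        for (phase in analysis_phases) {
          cell <- sub[sub$metric == met & sub$phase_or_segment == phase, ]
          if (!nrow(cell)) next
          # one value per participant per movement: mean across trials
          agg <- stats::aggregate(value ~ participant_id + movement,
                                  data = cell, FUN = mean)
          med <- iqr <- numeric(3)
          for (m in 1:3) {
            v <- agg$value[agg$movement == m]
            med[m] <- stats::median(v)
            iqr[m] <- stats::IQR(v, type = 7)
          }
          st <- rescale_movement_stats(med, iqr, metric = met, task = task,
                                       phase = phase)
          if (met %in% larger_is_better_metrics()) {
            st <- invert_larger_is_better(st)
          }
          for (rule in rules_for(task, phase, pasta_both_everywhere)) {
            f <- apply_rule(st, rule)
            f$controller_id <- ctrl
            findings[[length(findings) + 1L]] <- f
            rows[[length(rows) + 1L]] <- data.frame(
              controller_id = ctrl, task_id = task, phase = phase,
              metric = met, rule = rule$name, flagged = f$flagged,
              evaluable = st$evaluable, inverted = st$inverted,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "findings") <- findings
  out
}

#' Write a limb-position-effect report as JSON
#'
#' @param findings Output of [identify_lpe()].
#' @param path Output path.
#' @export
write_lpe_report <- function(findings, path) {
  fs <- attr(findings, "findings")
  j <- lapply(fs, function(f) {
    list(controller = f$controller_id, task = f$task, phase = f$phase,
         metric = f$metric, rule = f$rule, flagged = f$flagged,
         inverted = f$inverted,
         rescaled_medians = f$stats$rescaled_medians,
         rescaled_iqrs = f$stats$rescaled_iqrs,
         condition_results = f$condition_results,
         reason = f$reason)
  })
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
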