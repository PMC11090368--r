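#' Statistical comparison configuration
#'
#' @param alpha Significance level for omnibus gates and pairwise tests.
#' @param normality_alpha Alpha of the Shapiro-Wilk normality decision.
#' @return Object of class `promet_statscfg`.
#' @export
stats_config <- function(alpha = 0.05, normality_alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_promet("bad_config", "alpha must be in (0, 1)")
  structure(list(alpha = alpha, normality_alpha = normality_alpha),
            class = "promet_statscfg")
}

#' Average a metric table down to per-participant values
#'
#' Phase- and segment-level metrics are averaged over trials and movements
#' per participant (and phase/segment); trial-level metrics over trials;
#' task/controller-level values pass through. Participants missing one of
#' the controllers are excluded with a warning.
#'
#' @param metrics Metric-table data.frame for one metric name.
#' @return data.frame `participant_id, controller_id, cell, value` where
#'   `cell` is the phase/segment label or `"(all)"`.
#' @export
summarize_levels <- function(metrics) {
  validate_metric_table(metrics)
  if (length(unique(metrics$metric)) != 1L) {
    stop_promet("bad_stats", "summarize one metric at a time")
  }
  lvl <- unique(metrics$level)
  if (length(lvl) != 1L) stop_promet("bad_stats", "mixed analysis levels")
  metrics$cell <- if (lvl %in% c("phase", "movement_segment")) {
    metrics$phase_or_segment
  } else "(all)"
  agg <- stats::aggregate(value ~ participant_id + controller_id + cell,
                          data = metrics, FUN = mean)
  ctrls <- unique(agg$controller_id)
  if (length(ctrls) == 2L) {
    keep <- vapply(unique(agg$participant_id), function(p) {
      length(unique(agg$controller_id[agg$participant_id == p])) == 2L
    }, logical(1))
    dropped <- unique(agg$participant_id)[!keep]
    if (length(dropped)) {
      warn_promet("incomplete_participant",
                  "excluding participant(s) missing one controller: %s",
                  paste(dropped, collapse = ", "))
      agg <- agg[!agg$participant_id %in% dropped, ]
    }
  }
  agg[order(agg$participant_id, agg$controller_id, agg$cell), ]
}

#' Friedman rank statistic with ties correction
#'
#' Chi-square Friedman statistic computed from mean ranks within blocks,
#' with the standard tie correction, and its chi-square p-value on k - 1
#' degrees of freedom.
#'
#' @param x Numeric matrix, blocks (subjects) in rows, treatments in
#'   columns; no missing cells.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
friedman_statistic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop_promet("bad_stats", "need >= 2 blocks and >= 2 treatments")
  if (any(!is.finite(x))) stop_promet("bad_stats", "missing cells not allowed")
  R <- t(apply(x, 1, rank))
  stat <- (12 / (n * k * (k + 1))) * sum(colSums(R)^2) - 3 * n * (k + 1)
  ties <- apply(x, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (corr > 0) stat <- stat / corr else stat <- 0
  df <- k - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-factor repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject controller x phase design. For each effect
#' (controller, phase, interaction) an orthonormal contrast basis is
#' applied to the subject x cell matrix; the univariate F is
#' `(SS_effect / q) / (SS_error / (q (n - 1)))` and the Greenhouse-Geisser
#' epsilon is `tr(S)^2 / (q tr(S^2))` for the contrast covariance `S`.
#' Corrected p-values use epsilon-scaled degrees of freedom. For a
#' two-level factor epsilon is identically 1.
#'
#' @param y Numeric matrix, subjects in rows, cells in columns ordered
#'   controller-major (controller 1 cells for all phases, then controller 2).
#' @param k Number of phase levels.
#' @return data.frame with effect, F, df1, df2, epsilon, p_gg.
#' @export
rmanova_gg <- function(y, k) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (ncol(y) != 2L * k) stop_promet("bad_stats", "expected 2 x k cells")
  if (n < 3L) stop_promet("too_few_participants", "need >= 3 subjects")
  phase_basis <- function(k) {
    if (k == 1L) return(matrix(numeric(0), 1, 0))
    C <- stats::contr.helmert(k)
    qr.Q(qr(C))  # orthonormal columns spanning the contrast space
  }
  ctrl <- matrix(c(1, -1) / sqrt(2), 2, 1)
  ones_k <- matrix(1 / sqrt(k), k, 1)
  ones_2 <- matrix(1 / sqrt(2), 2, 1)
  P <- phase_basis(k)
  effects <- list(controller = kronecker(ctrl, ones_k),
                  phase = kronecker(ones_2, P),
                  interaction = kronecker(ctrl, P))
  rows <- lapply(names(effects), function(nm) {
    C <- effects[[nm]]
    q <- ncol(C)
    if (q == 0L) return(NULL)
    Z <- y %*% C
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    resid <- sweep(Z, 2, zbar)
    ss_err <- sum(resid^2)
    S <- crossprod(resid) / (n - 1)
    eps <- if (q == 1L) 1 else {
      e <- sum(diag(S))^2 / (q * sum(S * S))
      max(min(e, 1), 1 / q)
    }
    Fv <- if (ss_err <= 1e-300) {
      if (ss_eff <= 1e-300) NaN else Inf
    } else (ss_eff / q) / (ss_err / (q * (n - 1)))
    p <- if (is.nan(Fv)) 1 else {
      stats::pf(Fv, eps * q, eps * q * (n - 1), lower.tail = FALSE)
    }
    data.frame(effect = nm, F = Fv, df1 = q, df2 = q * (n - 1),
               epsilon = eps, p_gg = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Paired comparison with degenerate-difference handling.
paired_test <- function(a, b, normal) {
  d <- a - b
  if (stats::sd(d) < 1e-12) {
    return(list(test = if (normal) "paired t" else "wilcoxon", p = 1,
                direction = 0, degenerate = TRUE))
  }
  if (normal) {
    ht <- stats::t.test(a, b, paired = TRUE)
    list(test = "paired t", p = ht$p.value, direction = sign(mean(d)),
         degenerate = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
    list(test = "wilcoxon", p = ht$p.value,
         direction = sign(stats::median(d)), degenerate = FALSE)
  }
}

#' Controller comparison for one metric
#'
#' Implements the comparison decision tree for a two-controller
#' repeated-measures design. Phase/segment-level metrics: Shapiro-Wilk on
#' the phase-centered controller differences decides the branch; the normal
#' branch runs the controller x phase RMANOVA and gates pairwise paired
#' t-tests per phase on a Greenhouse-Geisser-corrected controller effect or
#' interaction below alpha; the non-normal branch gates pairwise Wilcoxon
#' signed-rank tests per phase on a Friedman test over controllers (blocks
#' = participant x phase cells). Single-level metrics (trial/task/
#' controller averages) go straight to the pairwise test. Pairwise results
#' are reported as significant only when the applicable gate passed and
#' the pairwise p is below alpha.
#'
#' @param summarized Output of [summarize_levels()]: one row per
#'   participant x controller x cell.
#' @param cfg A [stats_config()].
#' @return Object of class `promet_comparison`: list with `omnibus`
#'   (data.frame) and `pairwise` (data.frame with p, direction,
#'   significant per cell).
#' @export
compare_metric <- function(summarized, cfg = stats_config()) {
  ctrls <- sort(unique(summarized$controller_id))
  if (length(ctrls) != 2L) stop_promet("bad_stats", "need exactly 2 controllers")
  cells <- sort(unique(summarized$cell))
  parts <- sort(unique(summarized$participant_id))
  if (length(parts) < 3L) stop_promet("too_few_participants", "need >= 3 participants")
  val <- function(p, c, cell) {
    v <- summarized$value[summarized$participant_id == p &
                            summarized$controller_id == c &
                            summarized$cell == cell]
    if (length(v) != 1L) stop_promet("bad_stats", "incomplete table for %s/%s/%s", p, c, cell)
    v
  }
  A <- sapply(cells, function(cl) sapply(parts, val, c = ctrls[1], cell = cl))
  B <- sapply(cells, function(cl) sapply(parts, val, c = ctrls[2], cell = cl))
  A <- matrix(A, nrow = length(parts)); B <- matrix(B, nrow = length(parts))
  D <- A - B
  centered <- sweep(D, 2, colMeans(D))
  normal <- if (stats::sd(as.vector(centered)) < 1e-12) TRUE else {
    stats::shapiro.test(as.vector(centered))$p.value > cfg$normality_alpha
  }
  multi <- length(cells) > 1L
  omnibus <- NULL
  gate <- TRUE
  if (multi) {
    if (normal) {
      an <- rmanova_gg(cbind(A, B), k = length(cells))
      gate <- any(an$p_gg[an$effect %in% c("controller", "interaction")] <
                    cfg$alpha, na.rm = TRUE)
      omnibus <- data.frame(test = "RMANOVA (GG)", effect = an$effect,
                            statistic = an$F, epsilon = an$epsilon,
                            p = an$p_gg, stringsAsFactors = FALSE)
    } else {
      fr <- friedman_statistic(cbind(as.vector(A), as.vector(B)))
      gate <- fr$p_value < cfg$alpha
      omnibus <- data.frame(test = "Friedman", effect = "controller",
                            statistic = fr$statistic, epsilon = NA,
                            p = fr$p_value, stringsAsFactors = FALSE)
    }
  }
  pairwise <- do.call(rbind, lapply(seq_along(cells), function(j) {
    pt <- paired_test(A[, j], B[, j], normal)
    data.frame(cell = cells[j], test = pt$test, p = pt$p,
               direction = pt$direction, degenerate = pt$degenerate,
               significant = gate && !pt$degenerate && pt$p < cfg$alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(controllers = ctrls, normal = normal, gate_passed = gate,
                 omnibus = omnibus, pairwise = pairwise,
                 note = "p-values are raw (no across-metric correction)"),
            class = "promet_comparison")
}

#' @export
print.promet_comparison <- function(x, ...) {
  cat(sprintf("<promet_comparison> %s vs %s | %s branch | gate %s\n",
              x$controllers[1], x$controllers[2],
              if (x$normal) "normal (RMANOVA)" else "non-normal (Friedman)",
              if (x$gate_passed) "passed" else "failed"))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Compare two controllers across all metrics of a table
#'
#' Runs [summarize_levels()] and [compare_metric()] per metric name and
#' task, and collects one row per metric x task x cell.
#'
#' @param metrics Metric-table data.frame (both controllers).
#' @param cfg A [stats_config()].
#' @return data.frame comparison report.
#' @export
compare_controllers <- function(metrics, cfg = stats_config()) {
  validate_metric_table(metrics)
  rows <- list()
  for (met in unique(metrics$metric)) {
    for (task in unique(metrics$task_id[metrics$metric == met])) {
      sub <- metrics[metrics$metric == met & metrics$task_id == task, ]
      if (length(unique(sub$controller_id)) != 2L) next
      sm <- summarize_levels(sub)
      cmp <- tryCatch(compare_metric(sm, cfg), promet_error = function(e) NULL)
      if (is.null(cmp)) next
      pw <- cmp$pairwise
      pw$metric <- met; pw$task_id <- task
      pw$omnibus_test <- if (is.null(cmp$omnibus)) "(none)" else cmp$omnibus$test[1]
      pw$gate_passed <- cmp$gate_passed
      rows[[length(rows) + 1L]] <- pw
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(cell = character(), test = character(), p = numeric(),
               direction = numeric(), degenerate = logical(),
               significant = logical(), metric = character(),
               task_id = character(), omnibus_test = character(),
               gate_passed = logical(), stringsAsFactors = FALSE)
  }
  attr(out, "note") <- "p-values are raw (no across-metric correction)"
  out
}

#' Aggregate user-experience survey scores
#'
#' Validates score ranges (NASA-TLX dimensions 0-100, usability dimensions
#' 0-5), computes per-dimension across-participant medians and IQRs per
#' controller, and a paired Wilcoxon signed-rank test per dimension at the
#' controller level.
#'
#' @param responses data.frame with columns `participant_id`,
#'   `controller_id`, `instrument` (`"nasa_tlx"` or `"usability"`),
#'   `dimension`, `score`.
#' @return data.frame per dimension x controller with `median`, `iqr` and
#'   per-dimension `p_value` (paired Wilcoxon), plus `degenerate`.
#' @export
aggregate_surveys <- function(responses) {
  need <- c("participant_id", "controller_id", "instrument", "dimension", "score")
  miss <- setdiff(need, names(responses))
  if (length(miss)) {
    stop_promet("missing_column", "survey table lacks: %s",
                paste(miss, collapse = ", "))
  }
  lim <- c(nasa_tlx = 100, usability = 5)
  bad <- !responses$instrument %in% names(lim)
  if (any(bad)) {
    stop_promet("bad_survey", "unknown instrument: %s",
                paste(unique(responses$instrument[bad]), collapse = ", "))
  }
  out_of_scale <- responses$score < 0 |
    responses$score > lim[responses$instrument]
  if (any(out_of_scale)) {
    stop_promet("bad_survey", "score outside its scale (e.g. %g on %s)",
                responses$score[out_of_scale][1],
                responses$instrument[out_of_scale][1])
  }
  ctrls <- sort(unique(responses$controller_id))
  if (length(ctrls) != 2L) stop_promet("bad_survey", "need exactly 2 controllers")
  rows <- list()
  for (ins in unique(responses$instrument)) {
    for (dim in unique(responses$dimension[responses$instrument == ins])) {
      sub <- responses[responses$instrument == ins & responses$dimension == dim, ]
      parts <- sort(unique(sub$participant_id))
      a <- vapply(parts, function(p) {
        sub$score[sub$participant_id == p & sub$controller_id == ctrls[1]][1]
      }, numeric(1))
      b <- vapply(parts, function(p) {
        sub$score[sub$participant_id == p & sub$controller_id == ctrls[2]][1]
      }, numeric(1))
      if (any(is.na(a)) || any(is.na(b))) {
        stop_promet("bad_survey", "each participant needs both controllers (%s/%s)",
                    ins, dim)
      }
      pt <- paired_test(a, b, normal = FALSE)
      for (i in 1:2) {
        v <- if (i == 1) a else b
        rows[[length(rows) + 1L]] <- data.frame(
          instrument = ins, dimension = dim, controller_id = ctrls[i],
          median = stats::median(v), iqr = stats::IQR(v, type = 7),
          p_value = pt$p, degenerate = pt$degenerate, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a comparison report as JSON
#'
#' @param report Output of [compare_controllers()].
#' @param path Output path.
#' @export
write_comparison_report <- function(report, path) {
  j <- list(note = attr(report, "note"),
            comparisons = report)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
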