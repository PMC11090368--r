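test_that("per-participant summaries average over trials and movements", {
  df <- rbind(
    metric_record("P1", "A", "PASTA", "m", "phase", 1, movement = 1,
                  trial_index = 1, phase_or_segment = "Grasp"),
    metric_record("P1", "A", "PASTA", "m", "phase", 2, movement = 2,
                  trial_index = 1, phase_or_segment = "Grasp"),
    metric_record("P1", "A", "PASTA", "m", "phase", 3, movement = 3,
                  trial_index = 1, phase_or_segment = "Grasp"))
  sm <- summarize_levels(df)
  expect_equal(sm$value, 2)

  one <- metric_record("P1", "A", "PASTA", "m", "trial", 7.5, trial_index = 1)
  expect_equal(summarize_levels(one)$value, 7.5)

  # unbalanced trial counts: means over available trials
  df2 <- rbind(df, df[1, ])
  df2$trial_index <- c(1L, 1L, 1L, 2L)
  df2$value <- c(1, 2, 3, 10)
  expect_equal(summarize_levels(df2)$value, mean(c(1, 2, 3, 10)))

  # a participant missing one controller is excluded with a warning
  df3 <- rbind(make_phase_table(4),
               metric_record("P9", "A", "PASTA", "m", "phase", 5,
                             trial_index = 1, movement = 1,
                             phase_or_segment = "Reach"))
  expect_warning(sm3 <- summarize_levels(df3),
                 class = "promet_incomplete_participant")
  expect_false("P9" %in% sm3$participant_id)
})

test_that("identical arms never test significant; strong shifts always do", {
  same <- make_phase_table(8, shift = 0, seed = 30)
  same$value[same$controller_id == "B"] <-
    same$value[same$controller_id == "A"]
  c0 <- compare_metric(summarize_levels(same))
  expect_false(any(c0$pairwise$significant))
  expect_true(all(c0$pairwise$degenerate))
  expect_true(all(c0$pairwise$p == 1))

  c1 <- compare_metric(summarize_levels(make_phase_table(8, shift = 10,
                                                         seed = 31)))
  expect_true(all(c1$pairwise$significant))

  expect_error(compare_metric(summarize_levels(make_phase_table(2))),
               class = "promet_too_few_participants")
})

test_that("swapping controller labels preserves p and negates direction", {
  sm <- summarize_levels(make_phase_table(8, shift = 2, seed = 32))
  a <- compare_metric(sm)
  sm2 <- sm
  sm2$controller_id <- ifelse(sm$controller_id == "A", "B", "A")
  b <- compare_metric(sm2)
  expect_equal(a$pairwise$p, b$pairwise$p, tolerance = 1e-12)
  expect_equal(a$pairwise$direction, -b$pairwise$direction)
})

test_that("Greenhouse-Geisser epsilon is 1 for two-level factors and the RM
          ANOVA matches an aov error-stratum oracle", {
  set.seed(33)
  y2 <- matrix(rnorm(8 * 4), 8, 4)
  an2 <- rmanova_gg(y2, k = 2)
  expect_equal(an2$epsilon, c(1, 1, 1))

  # oracle: univariate repeated-measures aov with Error strata
  n <- 10; k <- 3
  y <- matrix(rnorm(n * 2 * k, 10), n, 2 * k)
  an <- rmanova_gg(y, k = k)
  long <- data.frame(
    value = as.vector(y),
    subj = factor(rep(seq_len(n), 2 * k)),
    ctrl = factor(rep(rep(1:2, each = k), each = n)[seq_len(n * 2 * k)]))
  long$ctrl <- factor(rep(1:2, each = n * k))
  long$phase <- factor(rep(rep(seq_len(k), each = n), 2))
  fit <- summary(stats::aov(value ~ ctrl * phase +
                              Error(subj / (ctrl * phase)), data = long))
  f_ctrl <- fit[["Error: subj:ctrl"]][[1]]["ctrl", "F value"]
  f_phase <- fit[["Error: subj:phase"]][[1]]["phase", "F value"]
  f_int <- fit[["Error: subj:ctrl:phase"]][[1]]["ctrl:phase", "F value"]
  expect_equal(an$F[an$effect == "controller"], f_ctrl, tolerance = 1e-8)
  expect_equal(an$F[an$effect == "phase"], f_phase, tolerance = 1e-8)
  expect_equal(an$F[an$effect == "interaction"], f_int, tolerance = 1e-8)

  # two-level controller effect equals the squared paired t statistic
  tstat <- stats::t.test(rowMeans(y[, 1:k]), rowMeans(y[, k + 1:k]),
                         paired = TRUE)$statistic
  expect_equal(an$F[an$effect == "controller"], unname(tstat^2),
               tolerance = 1e-8)
})

test_that("Friedman statistic matches the rank formula and stats::friedman.test", {
  set.seed(34)
  for (i in 1:200) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k), n, k)
    got <- friedman_statistic(x)
    expect_equal(got$statistic, oracle_friedman(x), tolerance = 1e-12)
    ft <- stats::friedman.test(x)
    expect_equal(got$statistic, unname(ft$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ft$p.value, tolerance = 1e-12)
  }
  # perfectly consistent ranking with k = 3: statistic = 2n
  x <- t(replicate(5, c(0, 1, 2))) + matrix(rnorm(15, 0, 1e-3), 5, 3)
  expect_equal(friedman_statistic(x)$statistic, 10)
  # k = 2 with one column always larger reduces to n
  x2 <- cbind(rnorm(7), rnorm(7) + 10)
  expect_equal(friedman_statistic(x2)$statistic, 7)
  expect_equal(friedman_statistic(matrix(c(1, 2, 1, 2), 2, 2))$statistic, 0)
  expect_error(friedman_statistic(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "promet_bad_stats")
})

test_that("pairwise significance is gated on the omnibus decision", {
  # interaction-free, tiny controller effect + huge phase effect: the gate
  # must reflect only controller terms, so pairwise stays non-significant
  set.seed(35)
  n <- 8; k <- 4
  phase_means <- c(0, 50, 100, 150)
  A <- t(replicate(n, phase_means + rnorm(k)))
  B <- A + rnorm(n * k, 0, 0.1)  # noise only, no systematic shift
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(data.frame(participant_id = sprintf("P%d", i), controller_id = "A",
                     task_id = "T", metric = "m", level = "phase",
                     trial_index = 1L, movement = 1L,
                     phase_or_segment = c("Grasp", "Reach", "Release", "Transport"),
                     value = A[i, ], units = ""),
          data.frame(participant_id = sprintf("P%d", i), controller_id = "B",
                     task_id = "T", metric = "m", level = "phase",
                     trial_index = 1L, movement = 1L,
                     phase_or_segment = c("Grasp", "Reach", "Release", "Transport"),
                     value = B[i, ], units = ""))
  }))
  cmp <- compare_metric(summarize_levels(df))
  if (!cmp$gate_passed) expect_false(any(cmp$pairwise$significant))
  # invariant: significant implies gate passed, for all branches tried
  for (seed in 36:40) {
    cmp2 <- compare_metric(summarize_levels(make_phase_table(8, shift = runif(1, 0, 1),
                                                             seed = seed)))
    if (any(cmp2$pairwise$significant)) expect_true(cmp2$gate_passed)
  }
})

test_that("survey aggregation validates scales and finds shifted dimensions", {
  mk <- function(n = 8, shift_dim = NULL, shift = 20) {
    dims <- c("mental", "physical", "temporal", "effort")
    do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(dims, function(d) {
        base <- 40 + 5 * stats::rnorm(2)
        if (!is.null(shift_dim) && d == shift_dim) base[2] <- base[2] + shift
        data.frame(participant_id = sprintf("P%d", i),
                   controller_id = c("A", "B"), instrument = "nasa_tlx",
                   dimension = d, score = pmin(pmax(base, 0), 100))
      }))
    }))
  }
  set.seed(41)
  const <- mk(8)
  const$score <- 50
  agg <- aggregate_surveys(const)
  expect_equal(unique(agg$median), 50)
  expect_equal(unique(agg$iqr), 0)
  expect_true(all(agg$degenerate))

  bad <- mk(4)
  bad$instrument <- "usability"
  bad$score[1] <- 5.5
  expect_error(aggregate_surveys(bad), class = "promet_bad_survey")

  set.seed(42)
  shifted <- mk(8, shift_dim = "temporal", shift = 30)
  agg2 <- aggregate_surveys(shifted)
  p_by_dim <- tapply(agg2$p_value, agg2$dimension, unique)
  expect_equal(names(which.min(p_by_dim)), "temporal")
})

test_that("whole-table comparison reports one row per metric, task and cell", {
  df <- rbind(make_phase_table(8, shift = 10, seed = 43),
              transform(make_phase_table(8, shift = 0, seed = 44),
                        metric = "m2"))
  rep <- compare_controllers(df)
  expect_setequal(unique(rep$metric), c("m", "m2"))
  expect_equal(nrow(rep), 8)  # 2 metrics x 4 phases
  expect_true(all(rep$significant[rep$metric == "m"]))
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison_report(rep, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_match(j$note, "raw")
})
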