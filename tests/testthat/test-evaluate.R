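test_that("sensitivity, specificity and accuracy follow the printed formulas", {
  m <- metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_identical(m$sensitivity, 0.9)
  expect_identical(m$specificity, 0.8)
  expect_identical(m$accuracy, 0.85)

  m <- metrics(list(TP = 5, FN = 5, TN = 5, FP = 5))
  expect_identical(unlist(m), c(sensitivity = 0.5, specificity = 0.5, accuracy = 0.5))

  m <- metrics(list(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_identical(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))

  expect_error(metrics(list(TP = 0, FN = 0, TN = 5, FP = 5)), "sensitivity undefined")
})

test_that("confusion counts add up and feed pooled metrics consistently", {
  set.seed(71)
  truth <- sample(c("patient", "control"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth,
                 ifelse(truth == "patient", "control", "patient"))
  cc <- confusion_counts(truth, pred)
  expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 200L)
  expect_equal(metrics(cc)$accuracy, mean(truth == pred))
})

test_that("per-subject feature tables report mean and sample SD per channel", {
  f <- data.frame(
    subject_id = rep(c("P1", "C1"), each = 4),
    group = rep(c("patient", "control"), each = 4),
    channel = "Cz", window_index = rep(0:3, 2), feature = "apen",
    value = c(0.5, 0.5, 0.5, 0.5, 0.4, 0.6, 0.4, 0.6),
    stringsAsFactors = FALSE)
  tab <- subject_apen_table(f, "Cz")
  expect_identical(tab$mean[tab$subject_id == "P1"], 0.5)
  expect_identical(tab$sd[tab$subject_id == "P1"], 0)
  expect_equal(tab$sd[tab$subject_id == "C1"], sd(c(0.4, 0.6, 0.4, 0.6)))

  # two windows {0.4, 0.6}: 0.5 +/- 0.1414 (sample SD)
  f2 <- f[f$window_index < 2 & f$subject_id == "C1", ]
  tab2 <- subject_apen_table(f2, "Cz")
  expect_equal(tab2$mean, 0.5)
  expect_equal(tab2$sd, sqrt(0.02), tolerance = 1e-12)  # prints as 0.1414

  expect_error(subject_apen_table(f, "F3"), "F3")
  expect_error(subject_apen_table(f[f$window_index == 0, ], "Cz"), "at least 2")
})

test_that("controls show higher ApEn than patients in most generated cohorts", {
  wins <- vapply(1:8, function(seed) {
    cohort <- generate_cohort(cohort_spec(n_patients = 3, n_controls = 3,
                                          duration = 10, seed = seed))
    feats <- cohort_features(cohort, type = "apen",
                             windowing = windowing_params())
    ok <- vapply(c("Cz", "C3", "C4", "T3", "T4"), function(ch) {
      tab <- subject_apen_table(feats, ch)
      mean(tab$mean[tab$group == "control"]) > mean(tab$mean[tab$group == "patient"])
    }, logical(1))
    all(ok)
  }, logical(1))
  expect_gte(sum(wins), 7)
})

test_that("feature comparison statistics match the textbook formulas", {
  acc <- list(apen = c(0.9, 0.8, 0.95, 0.85, 0.9), other = c(0.7, 0.75, 0.8, 0.6, 0.72))
  cmp <- compare_features(acc)
  oracle <- paired_t_naive(acc$apen, acc$other)
  expect_equal(cmp$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(cmp$F_statistic, var(acc$other) / var(acc$apen), tolerance = 1e-12)

  # two fixed 20-fold vectors
  set.seed(81)
  a <- round(runif(20, 0.7, 1), 3)
  b <- round(runif(20, 0.5, 0.9), 3)
  cmp2 <- compare_features(list(apen = a, bp = b))
  oracle2 <- paired_t_naive(a, b)
  expect_equal(cmp2$t_statistic, oracle2$t, tolerance = 1e-10)
  expect_equal(cmp2$p_value, oracle2$p, tolerance = 1e-10)
})

test_that("degenerate comparisons are flagged, identical vectors are null", {
  v <- c(0.8, 0.85, 0.9, 0.8)
  same <- compare_features(list(apen = v, other = v))
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  expect_identical(same$F_statistic, 1)
  expect_false(same$degenerate)

  shifted <- compare_features(list(apen = v, other = v - 0.1))
  expect_true(shifted$degenerate)
  expect_lte(shifted$p_value, .Machine$double.xmin)

  expect_error(compare_features(list(apen = v, other = v[1:3])), "lengths differ")
})

test_that("pooled metrics equal the window-weighted combination of fold metrics", {
  fm <- local({
    set.seed(91)
    rows <- lapply(1:8, function(s) {
      g <- if (s <= 4) "patient" else "control"
      nw <- sample(8:15, 1)
      data.frame(subject_id = paste0("S", s), group = g, channel = "Cz",
                 window_index = seq_len(nw) - 1L, feature = "f",
                 value = rnorm(nw, mean = ifelse(g == "patient", 1.2, 0)),
                 stringsAsFactors = FALSE)
    })
    feature_matrix(do.call(rbind, rows))
  })
  res <- lopo_cv(fm)
  pooled <- metrics(res$confusion)$accuracy
  weighted <- sum(res$folds$accuracy * res$folds$n_windows) / sum(res$folds$n_windows)
  expect_equal(pooled, weighted, tolerance = 1e-12)
})
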