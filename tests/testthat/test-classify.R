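# two Gaussian clusters, far apart
make_separable <- function(n = 50, sep = 10, d = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d), ncol = d),
             matrix(rnorm(n * d, mean = sep), ncol = d))
  list(x = x, y = rep(c("patient", "control"), each = n))
}

# XOR layout: same-label clusters on opposite diagonal corners
make_xor <- function(n = 25, seed = 2) {
  set.seed(seed)
  centers <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  x <- do.call(rbind, lapply(1:4, function(i) {
    cbind(rnorm(n, centers[i, 1], 0.1), rnorm(n, centers[i, 2], 0.1))
  }))
  list(x = x, y = rep(c("patient", "patient", "control", "control"), each = n))
}

test_that("well-separated clusters are classified perfectly in training", {
  dat <- make_separable()
  model <- train_svm(dat$x, dat$y)
  pred <- predict(model, dat$x)
  expect_identical(pred$label, dat$y)
})

test_that("the RBF kernel shatters the XOR layout", {
  dat <- make_xor()
  model <- train_svm(dat$x, dat$y)
  expect_identical(predict(model, dat$x)$label, dat$y)
})

test_that("the dual solution satisfies the KKT conditions", {
  for (make in list(make_separable, make_xor)) {
    dat <- make()
    model <- train_svm(dat$x, dat$y, kernel_params(soft_margin_C = 1))
    expect_lt(abs(sum(model$coefs)), 1e-3)              # sum a_i y_i = 0
    expect_true(all(model$alpha >= 0 & model$alpha <= 1 + 1e-9))
  }
})

test_that("unbounded support vectors sit on the margin (|f| near 1)", {
  dat <- make_xor()
  model <- train_svm(dat$x, dat$y, kernel_params(soft_margin_C = 10))
  # recover decision values at the support vectors (already standardized)
  g <- 1 / (2 * model$sigma^2)
  K <- exp(-as.matrix(dist(model$sv))^2 * g)
  f_sv <- as.numeric(K %*% model$coefs) - model$b
  free <- model$alpha > 1e-6 & model$alpha < 10 - 1e-6
  expect_true(any(free))
  expect_equal(abs(f_sv[free]), rep(1, sum(free)), tolerance = 0.01)
})

test_that("the decision function equals a brute-force kernel sum", {
  dat <- make_xor()
  model <- train_svm(dat$x, dat$y)
  set.seed(3)
  probes <- matrix(rnorm(20), ncol = 2)
  fast <- predict(model, probes)$decision
  slow <- vapply(seq_len(nrow(probes)),
                 function(i) decision_bruteforce(model, probes[i, ]),
                 numeric(1))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("prediction validates dimensions and resolves ties to control", {
  dat <- make_separable()
  model <- train_svm(dat$x, dat$y)
  expect_error(predict(model, matrix(0, 1, 3)), "dimension")
  tied <- model
  tied$coefs <- rep(0, length(tied$coefs))
  tied$b <- 0
  expect_identical(predict(tied, matrix(0, 1, 2))$label, "control")
})

test_that("training rejects degenerate inputs", {
  dat <- make_separable()
  expect_error(train_svm(dat$x, rep("patient", nrow(dat$x))), "both classes")
  x_bad <- dat$x; x_bad[1, 1] <- NA
  expect_error(train_svm(x_bad, dat$y), "finite")
  expect_error(train_svm(dat$x, c("sick", "well")[1 + (dat$y == "control")]),
               "patient")
})

# small feature matrix built from a toy cohort
toy_fm <- function(n_per_group = 3, n_windows = 15, gap = 3, seed = 4) {
  set.seed(seed)
  rows <- list()
  for (g in c("patient", "control")) {
    for (s in seq_len(n_per_group)) {
      id <- paste0(substr(g, 1, 1), s)
      mu <- if (g == "patient") gap else 0
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = id, group = g, channel = "Cz",
        window_index = seq_len(n_windows) - 1L, feature = "f",
        value = rnorm(n_windows, mean = mu + rnorm(1, sd = 0.3)),
        stringsAsFactors = FALSE)
    }
  }
  feature_matrix(do.call(rbind, rows))
}

test_that("leave-one-participant-out holds each subject out exactly once", {
  fm <- toy_fm()
  res <- lopo_cv(fm)
  expect_identical(nrow(res$folds), 6L)
  expect_setequal(res$folds$subject_id, unique(fm$subject_id))
  expect_identical(anyDuplicated(res$folds$subject_id), 0L)
  expect_true(all(res$folds$accuracy >= 0 & res$folds$accuracy <= 1))
  # pooled predictions cover every window exactly once
  expect_identical(nrow(res$predictions), nrow(fm))
  # strong subject-level signal: near-perfect classification
  expect_gt(mean(res$folds$accuracy), 0.9)
})

test_that("fold results are invariant to subject and window ordering", {
  fm <- toy_fm()
  res1 <- lopo_cv(fm)
  set.seed(8)
  perm <- sample(nrow(fm))
  fm2 <- fm[perm, ]
  class(fm2) <- class(fm)
  res2 <- lopo_cv(fm2)
  o1 <- res1$folds[order(res1$folds$subject_id), c("subject_id", "accuracy")]
  o2 <- res2$folds[order(res2$folds$subject_id), c("subject_id", "accuracy")]
  expect_equal(o1$accuracy, o2$accuracy, tolerance = 1e-10)
})

test_that("subject-level label permutation destroys accuracy (leak detector)", {
  # generator-like statistics: continuous spread of subject means with
  # window noise on the same scale, so a permuted-label run has no usable
  # structure left
  cohort <- generate_cohort(cohort_spec(n_patients = 5, n_controls = 5,
                                        duration = 15, seed = 2))
  fm <- feature_matrix(cohort_features(cohort, type = "apen"))
  unpermuted <- mean(lopo_cv(fm)$folds$accuracy)
  mean_acc <- vapply(1:20, function(p) {
    mean(lopo_cv(permute_subject_labels(fm, seed = p))$folds$accuracy)
  }, numeric(1))
  expect_gt(unpermuted, 0.75)
  expect_lt(mean(mean_acc), 0.7)
  expect_gt(mean(mean_acc), 0.3)
})

test_that("lopo_cv validates its inputs", {
  fm <- toy_fm(n_per_group = 1)
  expect_error(lopo_cv(fm), "2 subjects per class")
  expect_error(lopo_cv(data.frame()), "feature_matrix")
})
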