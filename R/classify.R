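#' Kernel parameters for the maximum-margin classifier
#'
#' @param sigma RBF kernel width; `NULL` (with
#'   `sigma_policy = "median_heuristic"`) selects the median pairwise
#'   Euclidean distance between standardized training vectors.
#' @param soft_margin_C Box constraint on the dual coefficients (default 1).
#' @param sigma_policy `"median_heuristic"` (default) or `"fixed"` (requires
#'   `sigma`).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(sigma = NULL, soft_margin_C = 1,
                          sigma_policy = c("median_heuristic", "fixed")) {
  sigma_policy <- match.arg(sigma_policy)
  if (sigma_policy == "fixed") {
    stopifnot_msg(is.numeric(sigma) && sigma > 0, "fixed sigma must be > 0")
  } else if (!is.null(sigma)) {
    stopifnot_msg(is.numeric(sigma) && sigma > 0, "sigma must be > 0")
    sigma_policy <- "fixed"
  }
  stopifnot_msg(is.numeric(soft_margin_C) && soft_margin_C > 0,
                "soft_margin_C must be > 0")
  structure(list(sigma = sigma, soft_margin_C = soft_margin_C,
                 sigma_policy = sigma_policy),
            class = "kernel_params")
}

# median pairwise Euclidean distance; for large n a deterministic stride
# subsample keeps the cost bounded
median_pairwise_distance <- function(x, max_rows = 1024L) {
  n <- nrow(x)
  if (n > max_rows) {
    x <- x[seq(1L, n, length.out = max_rows), , drop = FALSE]
  }
  stats::median(stats::dist(x))
}

#' Train an RBF-kernel maximum-margin classifier
#'
#' Solves the soft-margin dual problem for a Gaussian-kernel support vector
#' machine: maximise `sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j k(x_i, x_j)`
#' subject to `0 <= a_i <= C` and `sum_i a_i y_i = 0`, with kernel
#' `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`.  The decision function is
#' `f(x) = sum_i a_i y_i k(x_i, x) - b`; the predicted label is its sign,
#' with patient mapped to +1 and ties (f = 0) resolved to control.
#'
#' Features are standardized with the training-set mean and SD before
#' training; the same transform is stored in the model and applied at
#' prediction time.  The quadratic programme is solved by the sequential
#' minimal optimisation solver of \pkg{e1071} (libsvm), which is
#' deterministic for fixed inputs.
#'
#' @param x Numeric matrix (or data frame) of feature vectors, one row per
#'   window.
#' @param y Labels: `"patient"` / `"control"` (or a factor/vector coercible
#'   to those two values).
#' @param params A [kernel_params()].
#' @return An object of class `kernel_classifier`: support vectors `sv`
#'   (standardized), signed dual coefficients `coefs` (`a_i y_i`), `alpha`
#'   (`a_i >= 0`), support labels `y_sv`, bias `b`, kernel width `sigma`,
#'   box constraint `C`, and the standardization `center` / `scale`.
#' @export
train_svm <- function(x, y, params = kernel_params()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("train_svm(): non-finite feature values")
  y <- as.character(y)
  if (!all(y %in% c("patient", "control"))) {
    stop("train_svm(): labels must be 'patient' or 'control'")
  }
  if (length(unique(y)) < 2) {
    stop("train_svm(): both classes must be present in the training set")
  }
  if (nrow(x) != length(y)) stop("train_svm(): x and y lengths differ")

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  sigma <- if (params$sigma_policy == "fixed") params$sigma else {
    s <- median_pairwise_distance(xs)
    if (!is.finite(s) || s <= 0) {
      stop("train_svm(): degenerate features, median pairwise distance is 0")
    }
    s
  }
  C <- params$soft_margin_C

  fit <- e1071::svm(xs, factor(y, levels = c("patient", "control")),
                    scale = FALSE, type = "C-classification",
                    kernel = "radial", gamma = 1 / (2 * sigma^2), cost = C)

  # orient the stored decision function so that f > 0 means patient
  coefs <- as.numeric(fit$coefs)
  b <- fit$rho
  sv <- as.matrix(fit$SV)
  k1 <- exp(-rowSums(sweep(sv, 2, xs[1, ])^2) / (2 * sigma^2))
  f1 <- sum(coefs * k1) - b
  p1 <- as.character(stats::predict(fit, xs[1, , drop = FALSE]))
  if ((f1 > 0) != (p1 == "patient")) {
    coefs <- -coefs
    b <- -b
  }

  structure(
    list(sv = sv, coefs = coefs, alpha = abs(coefs), y_sv = sign(coefs),
         b = b, sigma = sigma, C = C,
         center = center, scale = scale,
         feature_names = colnames(x)),
    class = "kernel_classifier"
  )
}

#' @export
print.kernel_classifier <- function(x, ...) {
  cat(sprintf("RBF maximum-margin classifier: %d support vectors, sigma = %.4g, C = %g\n",
              nrow(x$sv), x$sigma, x$C))
  invisible(x)
}

#' Predict with a trained kernel classifier
#'
#' Evaluates `f(x) = sum_i a_i y_i k(x_i, x) - b` and labels each row by the
#' sign of `f` (patient for positive, control otherwise — a tie at exactly
#' zero is resolved to control).
#'
#' @param object A `kernel_classifier`.
#' @param newdata Matrix or data frame of feature vectors with the training
#'   dimensionality.
#' @param ... Unused.
#' @return Data frame with columns `decision` (the value of `f`) and `label`
#'   (`"patient"` / `"control"`).
#' @export
predict.kernel_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$sv)) {
    stop("predict(): feature dimension ", ncol(newdata),
         " does not match training dimension ", ncol(object$sv))
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  g <- 1 / (2 * object$sigma^2)
  # ||u - v||^2 = ||u||^2 + ||v||^2 - 2 u.v, rows of xs against support vectors
  d2 <- outer(rowSums(xs^2), rowSums(object$sv^2), "+") -
    2 * tcrossprod(xs, object$sv)
  d2[d2 < 0] <- 0
  f <- as.numeric(exp(-g * d2) %*% object$coefs) - object$b
  data.frame(decision = f,
             label = ifelse(f > 0, "patient", "control"),
             stringsAsFactors = FALSE)
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per subject: all windows of the held-out subject form the test
#' set and every other subject's windows form the training set.  Feature
#' standardization and (if applicable) the median-heuristic kernel width are
#' computed inside each training fold only, so the held-out subject never
#' influences training in any way.  Fold accuracy is the fraction of the
#' held-out subject's windows classified correctly (window-level scoring); a
#' subject-level majority vote is reported alongside.
#'
#' @param fm A [feature_matrix()].
#' @param params A [kernel_params()].
#' @return An object of class `lopo_result`: `folds` (one row per subject:
#'   `subject_id`, `group`, `n_windows`, `accuracy`, `majority_label`,
#'   `sigma`), `predictions` (pooled per-window predictions), `confusion`
#'   (pooled counts via [confusion_counts()]), and the kernel settings.
#' @export
lopo_cv <- function(fm, params = kernel_params()) {
  if (!inherits(fm, "feature_matrix")) {
    stop("lopo_cv(): fm must be a feature_matrix")
  }
  meta <- c("subject_id", "group", "window_index")
  feat_cols <- setdiff(names(fm), meta)
  subjects <- unique(fm$subject_id)
  grp_of <- fm$group[match(subjects, fm$subject_id)]
  if (length(unique(grp_of)) < 2 || min(table(grp_of)) < 2) {
    stop("lopo_cv(): need at least 2 subjects per class")
  }
  if (any(table(fm$subject_id) == 0)) stop("lopo_cv(): subject with zero windows")

  x_all <- as.matrix(fm[feat_cols])
  folds <- vector("list", length(subjects))
  preds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test <- fm$subject_id == s
    model <- train_svm(x_all[!test, , drop = FALSE], fm$group[!test], params)
    p <- predict(model, x_all[test, , drop = FALSE])
    truth <- fm$group[test]
    folds[[i]] <- data.frame(
      subject_id = s, group = grp_of[i], n_windows = sum(test),
      accuracy = mean(p$label == truth),
      majority_label = if (mean(p$label == "patient") > 0.5) "patient" else "control",
      sigma = model$sigma,
      stringsAsFactors = FALSE
    )
    preds[[i]] <- data.frame(
      subject_id = s, group = truth,
      window_index = fm$window_index[test],
      decision = p$decision, label = p$label,
      stringsAsFactors = FALSE
    )
  }
  folds <- do.call(rbind, folds)
  predictions <- do.call(rbind, preds)
  structure(
    list(folds = folds, predictions = predictions,
         confusion = confusion_counts(predictions$group, predictions$label),
         params = params),
    class = "lopo_result"
  )
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("Leave-one-participant-out CV: %d folds, accuracy %.4f +/- %.4f\n",
              nrow(x$folds), mean(x$folds$accuracy), stats::sd(x$folds$accuracy)))
  invisible(x)
}

#' Permute group labels at the subject level
#'
#' Reassigns the existing group labels to subjects uniformly at random while
#' keeping every window of a subject together.  Used as a leak detector: with
#' permuted labels a sound cross-validation protocol must fall to chance
#' accuracy.
#'
#' @param fm A [feature_matrix()].
#' @param seed Integer seed for the permutation.
#' @return The feature matrix with permuted `group` labels.
#' @export
permute_subject_labels <- function(fm, seed) {
  subjects <- unique(fm$subject_id)
  grp <- fm$group[match(subjects, fm$subject_id)]
  set.seed(seed)
  newgrp <- sample(grp)
  fm$group <- newgrp[match(fm$subject_id, subjects)]
  fm
}
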