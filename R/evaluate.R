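#' Confusion counts with patient as the positive class
#'
#' @param truth,predicted Character vectors of `"patient"` / `"control"`.
#' @return An object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot_msg(length(truth) == length(predicted),
                "truth and predicted must have equal length")
  structure(
    list(TP = sum(truth == "patient" & predicted == "patient"),
         TN = sum(truth == "control" & predicted == "control"),
         FP = sum(truth == "control" & predicted == "patient"),
         FN = sum(truth == "patient" & predicted == "control")),
    class = "confusion_counts"
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' With patient as the positive class: sensitivity (true-positive ratio)
#' `TP / (TP + FN)`, specificity (true-negative ratio) `TN / (TN + FP)`,
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion_counts()] object or a list with fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named list `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
#' @export
metrics <- function(c) {
  cnt <- lapply(c[c("TP", "TN", "FP", "FN")], as.numeric)
  if (any(vapply(cnt, function(v) length(v) != 1 || is.na(v) || v < 0, TRUE))) {
    stop("metrics(): TP, TN, FP, FN must be nonnegative counts")
  }
  if (cnt$TP + cnt$FN == 0) stop("metrics(): no positive (patient) samples; sensitivity undefined")
  if (cnt$TN + cnt$FP == 0) stop("metrics(): no negative (control) samples; specificity undefined")
  list(sensitivity = cnt$TP / (cnt$TP + cnt$FN),
       specificity = cnt$TN / (cnt$TN + cnt$FP),
       accuracy = (cnt$TP + cnt$TN) / (cnt$TP + cnt$TN + cnt$FP + cnt$FN))
}

#' Per-subject summary table of windowed ApEn (or any scalar feature)
#'
#' For one channel, summarises each subject's window-level feature values as
#' mean and sample SD (n - 1 denominator) — the per-subject "mean ± SD"
#' layout conventionally reported per channel.
#'
#' @param features Long-format feature table ([cohort_features()]).
#' @param channel Channel name to summarise.
#' @param feature Feature name (default `"apen"`).
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `n_windows`, `mean`, `sd`.
#' @export
subject_apen_table <- function(features, channel, feature = "apen") {
  sub <- features[features$channel == channel & features$feature == feature, ]
  if (!nrow(sub)) {
    stop("subject_apen_table(): no '", feature, "' values for channel ", channel)
  }
  counts <- table(sub$subject_id)
  if (any(counts < 2)) {
    stop("subject_apen_table(): need at least 2 windows per subject")
  }
  agg <- do.call(rbind, lapply(split(sub, sub$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               n_windows = nrow(d), mean = mean(d$value),
               sd = stats::sd(d$value), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$group, agg$subject_id), ]
}

#' Compare fold-accuracy vectors between feature types
#'
#' For the reference feature (ApEn by default) against every other feature
#' type: the variance-ratio F statistic `var(other) / var(reference)` over
#' the matched fold accuracies, and a two-sided paired t-test over the same
#' folds.  No multiple-testing correction is applied across the comparisons;
#' the F orientation is recorded in the output.  A degenerate paired test
#' (zero variance of the differences but a nonzero mean difference) is
#' reported with `p_value` below the machine floor and `degenerate = TRUE`.
#'
#' @param fold_accuracies Named list of numeric vectors of per-fold
#'   accuracies, all the same length and fold order.
#' @param reference Name of the reference feature (default `"apen"`).
#' @return Data frame with one row per comparison: `reference`, `other`,
#'   `F_statistic` (var(other)/var(reference)), `t_statistic`, `p_value`,
#'   `degenerate`.
#' @export
compare_features <- function(fold_accuracies, reference = "apen") {
  if (!reference %in% names(fold_accuracies)) {
    stop("compare_features(): no '", reference, "' entry")
  }
  ref <- fold_accuracies[[reference]]
  others <- setdiff(names(fold_accuracies), reference)
  out <- lapply(others, function(nm) {
    v <- fold_accuracies[[nm]]
    if (length(v) != length(ref)) {
      stop("compare_features(): fold vector lengths differ for ", nm)
    }
    d <- ref - v
    n <- length(d)
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        t_stat <- 0; p <- 1; degen <- FALSE
      } else {
        t_stat <- sign(mean(d)) * Inf; p <- .Machine$double.xmin; degen <- TRUE
      }
    } else {
      tt <- stats::t.test(ref, v, paired = TRUE)
      t_stat <- unname(tt$statistic); p <- tt$p.value
      degen <- FALSE
    }
    data.frame(reference = reference, other = nm,
               F_statistic = stats::var(v) / stats::var(ref),
               t_statistic = t_stat, p_value = p, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
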