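#' Extract per-window features from a window set
#'
#' Applies one feature extractor to every window of every analysis channel.
#' Available feature types:
#' \describe{
#'   \item{`apen`}{approximate entropy ([apen()]); one value per window.}
#'   \item{`fd`}{Higuchi fractal dimension ([higuchi_fd()]); one value.}
#'   \item{`ar`}{Burg autoregressive coefficients ([burg_ar()]); `order`
#'     values named `ar_1 ... ar_P`.}
#'   \item{`bandpower`}{Butterworth band power ([band_power()]); one value
#'     per canonical band (`delta`, `theta`, `alpha`, `beta`).}
#' }
#'
#' @param ws A `window_set` from [segment()].
#' @param type Feature type, one of `"apen"`, `"fd"`, `"ar"`, `"bandpower"`.
#' @param apen_params List of arguments for [apen()] (`m`, `r_coefficient`,
#'   `self_match`).  The windowed analysis defaults to the classical
#'   self-match convention (`"include"`), under which the statistic is
#'   defined for every window of a stochastic signal.
#' @param higuchi_params List of arguments for [higuchi_fd()] (`k_max`).
#' @param ar_order Burg model order (default 10).
#' @param bands Band definitions for [band_power()].
#' @return A long-format data frame with columns `subject_id`, `group`,
#'   `channel`, `window_index` (0-based), `feature`, `value`.
#' @export
extract_features <- function(ws, type = c("apen", "fd", "ar", "bandpower"),
                             apen_params = list(m = 2, r_coefficient = 0.1,
                                                self_match = "include"),
                             higuchi_params = list(k_max = 8),
                             ar_order = 10,
                             bands = eeg_bands()) {
  type <- match.arg(type)
  if (!inherits(ws, "window_set")) {
    stop("extract_features(): ws must be a window_set")
  }
  apen_params <- utils::modifyList(
    list(m = 2, r_coefficient = 0.1, self_match = "include"), apen_params)
  fn <- switch(type,
    apen = function(x) c(apen = do.call(.apen_fast, c(list(x), apen_params))),
    fd = function(x) c(fd = do.call(higuchi_fd, c(list(x), higuchi_params))$D),
    ar = function(x) {
      a <- burg_ar(x, order = ar_order)$coefficients
      names(a) <- paste0("ar_", seq_along(a))
      a
    },
    bandpower = function(x) band_power(x, fs = ws$fs, bands = bands)
  )
  out <- lapply(names(ws$data), function(ch) {
    m <- ws$data[[ch]]
    vals <- apply(m, 2, fn)
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                           dimnames = list(names(fn(m[, 1]))))
    nfeat <- nrow(vals)
    data.frame(
      subject_id = ws$subject_id, group = ws$group, channel = ch,
      window_index = rep(seq_len(ncol(m)) - 1L, each = nfeat),
      feature = rep(rownames(vals), times = ncol(m)),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Extract features for a whole cohort
#'
#' Convenience wrapper: segments every recording and stacks the per-window
#' feature tables of [extract_features()].
#'
#' @param recordings List of `eeg_recording` objects.
#' @param windowing A [windowing_params()].
#' @param type,... Passed to [extract_features()].
#' @return Long-format feature data frame (see [extract_features()]).
#' @export
cohort_features <- function(recordings, windowing = windowing_params(),
                            type = "apen", ...) {
  do.call(rbind, lapply(recordings, function(rec) {
    extract_features(segment(rec, windowing), type = type, ...)
  }))
}

#' Reshape a long feature table into a per-window feature matrix
#'
#' Builds the classifier input: one row per (subject, window) with one column
#' per channel-feature combination, plus the subject and group labels used
#' for leave-one-participant-out fold construction.
#'
#' @param features Long-format data frame from [extract_features()] /
#'   [cohort_features()].
#' @return A data frame of class `feature_matrix` with columns `subject_id`,
#'   `group`, `window_index`, then one numeric column per
#'   `<channel>_<feature>` (channels in order of first appearance).
#' @export
feature_matrix <- function(features) {
  needed <- c("subject_id", "group", "channel", "window_index", "feature", "value")
  if (!all(needed %in% names(features))) {
    stop("feature_matrix(): input must have columns ", paste(needed, collapse = ", "))
  }
  channels <- unique(features$channel)
  feats <- unique(features$feature)
  cols <- as.vector(t(outer(channels, feats, paste, sep = "_")))
  key <- paste(features$subject_id, features$window_index, sep = "\r")
  ukey <- unique(key)
  col_of <- match(paste(features$channel, features$feature, sep = "_"), cols)
  row_of <- match(key, ukey)
  m <- matrix(NA_real_, nrow = length(ukey), ncol = length(cols),
              dimnames = list(NULL, cols))
  m[cbind(row_of, col_of)] <- features$value
  if (anyNA(m)) stop("feature_matrix(): incomplete feature table ",
                     "(some subject/window/channel combinations are missing)")
  first <- !duplicated(key)
  out <- cbind(
    data.frame(subject_id = features$subject_id[first],
               group = features$group[first],
               window_index = features$window_index[first],
               stringsAsFactors = FALSE),
    as.data.frame(m)
  )
  class(out) <- c("feature_matrix", "data.frame")
  out
}
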