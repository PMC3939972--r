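#' Windowing parameters
#'
#' Parameters for cutting each analysis channel into fixed-length,
#' overlapping windows: 2-second windows with 50% overlap on the five
#' central/temporal channels by default.
#'
#' @param window_seconds Window length in seconds (default 2).
#' @param overlap_fraction Fractional overlap between successive windows,
#'   in `[0, 1)` (default 0.5).
#' @param channels Channels to analyse (default Cz, C3, C4, T3, T4).
#' @return An object of class `windowing_params`.
#' @export
windowing_params <- function(window_seconds = 2, overlap_fraction = 0.5,
                             channels = c("Cz", "C3", "C4", "T3", "T4")) {
  stopifnot_msg(is.numeric(window_seconds) && window_seconds > 0,
                "window_seconds must be > 0")
  stopifnot_msg(is.numeric(overlap_fraction) && overlap_fraction >= 0 &&
                  overlap_fraction < 1,
                "overlap_fraction must be in [0, 1)")
  stopifnot_msg(is.character(channels) && length(channels) >= 1,
                "channels must be a non-empty character vector")
  structure(list(window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction,
                 channels = channels),
            class = "windowing_params")
}

# canonical 10-20 montage names and the newer temporal aliases
.montage_1020 <- c("Fp1", "Fp2", "Fpz", "F3", "F4", "F7", "F8", "Fz",
                   "C3", "C4", "Cz", "P3", "P4", "Pz",
                   "T3", "T4", "T5", "T6", "O1", "O2", "Oz",
                   "A1", "A2", "M1", "M2")
.channel_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

normalize_channel <- function(x, aliases = FALSE) {
  x <- trimws(x)
  if (aliases) {
    hit <- toupper(x) %in% names(.channel_aliases)
    x[hit] <- .channel_aliases[toupper(x)[hit]]
  }
  m <- match(toupper(x), toupper(.montage_1020))
  ifelse(is.na(m), x, .montage_1020[m])
}

#' Read one subject's recording from a delimited text file
#'
#' Reads a recording written by [write_cohort()] (or any delimited text file
#' whose header row holds channel names and whose columns hold samples).
#' Channel names are matched case-insensitively against 10-20 montage names;
#' optionally the newer temporal aliases (T7 for T3, T8 for T4, ...) are
#' accepted.
#'
#' @param path File path.
#' @param subject_id,group Subject identifier and group label
#'   (`"patient"`/`"control"`) attached to the recording, e.g. from a
#'   manifest row.
#' @param fs Sampling rate in Hz of the stored samples (default 200).
#' @param channels Channels that must be present; `NULL` keeps all columns.
#' @param aliases Accept montage aliases (default `FALSE`).
#' @return An `eeg_recording` object.
#' @export
read_recording <- function(path, subject_id, group, fs = 200,
                           channels = NULL, aliases = FALSE) {
  if (!file.exists(path)) stop("read_recording(): file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "", check.names = FALSE),
    error = function(e) stop("read_recording(): cannot parse ", path, ": ",
                             conditionMessage(e))
  )
  if (!nrow(df) || !ncol(df)) stop("read_recording(): empty file: ", path)
  if (!all(vapply(df, is.numeric, TRUE))) {
    stop("read_recording(): non-numeric samples in ", path)
  }
  have <- normalize_channel(names(df), aliases = aliases)
  names(df) <- have
  if (!is.null(channels)) {
    want <- normalize_channel(channels, aliases = aliases)
    missing <- channels[!toupper(want) %in% toupper(have)]
    if (length(missing)) {
      stop("read_recording(): channel(s) missing from ", path, ": ",
           paste(missing, collapse = ", "))
    }
    df <- df[match(toupper(want), toupper(have))]
    names(df) <- want
  }
  data <- t(as.matrix(df))
  if (!all(is.finite(data))) stop("read_recording(): non-finite samples in ", path)
  structure(
    list(subject_id = subject_id, group = group,
         channel_names = rownames(data), fs = fs, data = data),
    class = "eeg_recording"
  )
}

#' Read a whole cohort from a manifest
#'
#' @param directory Directory holding `manifest.csv` (columns
#'   `subject_id,group,filename`) and the per-subject files, as written by
#'   [write_cohort()].
#' @param fs Sampling rate in Hz (default 200).
#' @param channels,aliases Passed to [read_recording()].
#' @return List of `eeg_recording` objects in manifest order.
#' @export
read_cohort <- function(directory, fs = 200, channels = NULL, aliases = FALSE) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("read_cohort(): no manifest.csv in ", directory)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "filename")
  if (!all(needed %in% names(manifest))) {
    stop("read_cohort(): manifest must have columns ", paste(needed, collapse = ","))
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(directory, manifest$filename[i]),
                   subject_id = manifest$subject_id[i],
                   group = manifest$group[i],
                   fs = fs, channels = channels, aliases = aliases)
  })
}

#' Segment a recording into overlapping windows
#'
#' Cuts each analysis channel into windows of `round(window_seconds * fs)`
#' samples starting at samples `0, step, 2 * step, ...` (0-based, half-open
#' intervals), with `step = round(N * (1 - overlap_fraction))`.  Trailing
#' samples that do not fill a whole window are discarded, so every window has
#' the same length; the count per channel is `floor((L - N) / step) + 1`.
#'
#' @param recording An `eeg_recording`.
#' @param params A [windowing_params()].
#' @return An object of class `window_set`: a list with `subject_id`, `group`,
#'   `fs`, the window length `n_samples`, 0-based `starts`, and `data`, a
#'   named list (one entry per channel) of `n_samples x n_windows` matrices.
#' @export
segment <- function(recording, params = windowing_params()) {
  if (!inherits(recording, "eeg_recording")) {
    stop("segment(): recording must be an eeg_recording")
  }
  if (!inherits(params, "windowing_params")) {
    stop("segment(): params must be windowing_params")
  }
  N <- as.integer(round(params$window_seconds * recording$fs))
  if (N < 50) {
    stop("segment(): window of ", N,
         " samples is below the 50-point floor required for ApEn")
  }
  step <- as.integer(round(N * (1 - params$overlap_fraction)))
  if (step < 1) stop("segment(): overlap too high, step would be 0")
  L <- ncol(recording$data)
  if (L < N) {
    stop("segment(): recording ", recording$subject_id, " is shorter (", L,
         " samples) than one window (", N, ")")
  }
  missing <- params$channels[!toupper(params$channels) %in%
                               toupper(recording$channel_names)]
  if (length(missing)) {
    stop("segment(): channel(s) missing from recording ", recording$subject_id,
         ": ", paste(missing, collapse = ", "))
  }
  starts <- seq.int(0L, L - N, by = step)
  idx <- match(toupper(params$channels), toupper(recording$channel_names))
  data <- lapply(idx, function(j) {
    vapply(starts, function(s) recording$data[j, (s + 1):(s + N)], numeric(N))
  })
  names(data) <- params$channels
  structure(
    list(subject_id = recording$subject_id, group = recording$group,
         fs = recording$fs, n_samples = N, starts = starts, data = data),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set %s (%s): %d windows x %d samples on %d channels\n",
              x$subject_id, x$group, length(x$starts), x$n_samples,
              length(x$data)))
  invisible(x)
}

#' Number of windows per channel in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) length(ws$starts)

#' Samples of one window
#'
#' @param ws A `window_set`.
#' @param channel Channel name.
#' @param index 0-based window ordinal (matching the `window_index` column of
#'   feature tables).
#' @return Numeric vector of samples.
#' @export
window_samples <- function(ws, channel, index) {
  m <- ws$data[[channel]]
  if (is.null(m)) stop("window_samples(): no channel ", channel)
  if (index < 0 || index >= ncol(m)) stop("window_samples(): index out of range")
  m[, index + 1]
}

#' Export windows as a long-format data frame (for debugging)
#'
#' @param ws A `window_set`.
#' @return Data frame with `subject_id`, `group`, `channel`, `window_index`
#'   and one column per sample (`s1 ... sN`).
#' @export
windows_to_df <- function(ws) {
  do.call(rbind, lapply(names(ws$data), function(ch) {
    m <- t(ws$data[[ch]])
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    cbind(data.frame(subject_id = ws$subject_id, group = ws$group,
                     channel = ch,
                     window_index = seq_len(nrow(m)) - 1L,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  }))
}
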