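#' Canonical EEG frequency bands
#'
#' The four classical EEG bands: delta 0-4 Hz, theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-30 Hz.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low_hz = c(0, 4, 8, 13),
             high_hz = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

# one filter per (fs, band, order); designed once and cached
.filter_cache <- new.env(parent = emptyenv())

band_filter <- function(fs, low_hz, high_hz, order = 5) {
  key <- paste(fs, low_hz, high_hz, order, sep = "|")
  filt <- .filter_cache[[key]]
  if (is.null(filt)) {
    nyq <- fs / 2
    if (low_hz <= 0) {
      # a 0 Hz lower edge cannot be a band-pass corner: low-pass at the
      # upper edge instead
      filt <- signal::butter(order, high_hz / nyq, type = "low")
    } else {
      filt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
    }
    rts <- Mod(polyroot(rev(filt$a)))
    if (any(rts >= 1)) {
      stop("band_filter(): unstable filter design for band ", low_hz, "-",
           high_hz, " Hz at fs = ", fs)
    }
    .filter_cache[[key]] <- filt
  }
  filt
}

#' Band power of a single window
#'
#' Filters the window into each canonical EEG band with a fifth-order
#' Butterworth filter (the delta band, whose lower edge is 0 Hz, uses a
#' low-pass at its upper edge) and reports the mean squared amplitude of the
#' filtered signal.  Filtering is zero-phase (forward-backward), so no phase
#' distortion is introduced within the short window; the effective magnitude
#' roll-off is doubled.  Using the mean rather than the sum of squares makes
#' the measure invariant to window length.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz; every band edge must lie below `fs / 2`.
#' @param bands Data frame of band definitions as from [eeg_bands()].
#' @param filter_order Butterworth design order, default 5.
#' @return Named numeric vector of band powers (amplitude-units squared),
#'   one entry per band, all non-negative.
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 10 * (0:399) / fs)   # 10 Hz tone: alpha band
#' band_power(x, fs)
#' @export
band_power <- function(x, fs, bands = eeg_bands(), filter_order = 5) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("band_power(): samples must be finite")
  if (!(fs > 0)) stop("band_power(): fs must be positive")
  if (any(bands$high_hz >= fs / 2)) {
    stop("band_power(): band edge at or above the Nyquist frequency ", fs / 2, " Hz")
  }
  if (any(bands$low_hz >= bands$high_hz)) {
    stop("band_power(): band lower edge must be below its upper edge")
  }
  if (length(x) < 3 * filter_order) {
    stop("band_power(): window too short for filter order ", filter_order)
  }
  out <- vapply(seq_len(nrow(bands)), function(i) {
    filt <- band_filter(fs, bands$low_hz[i], bands$high_hz[i], filter_order)
    y <- signal::filtfilt(filt, x)
    mean(y^2)
  }, numeric(1))
  names(out) <- bands$name
  out
}
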