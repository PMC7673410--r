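#' Construct a single-night EEG recording
#'
#' A `wn_recording` bundles one subject-night of multichannel EEG: a
#' channels-by-time matrix of samples in microvolts, channel labels, the
#' sampling rate, and subject/night identifiers. Inputs are assumed already
#' referenced (e.g. to linked mastoids); no re-referencing is performed.
#'
#' @param samples Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param subject_id Subject identifier.
#' @param night Night index (1 or 2).
#' @return An object of class `wn_recording`.
#' @export
recording <- function(samples, fs, channel_labels, subject_id = "S001", night = 1L) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("`samples` must be a numeric matrix")
  if (fs <= 0) abort("`fs` must be positive")
  if (length(channel_labels) != nrow(samples)) {
    abort("`channel_labels` must have one entry per channel (row) of `samples`")
  }
  if (anyDuplicated(channel_labels)) abort("duplicate channel labels")
  rownames(samples) <- channel_labels
  structure(
    list(subject_id = subject_id, night = as.integer(night), fs = fs,
         channel_labels = as.character(channel_labels), samples = samples),
    class = "wn_recording"
  )
}

#' @export
print.wn_recording <- function(x, ...) {
  cat(sprintf("<wn_recording> %s night %d: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$night, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

# symmetric Hann window
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# One-sided Hann-tapered periodogram of each row-epoch of `xmat`
# (epochs x samples). Returns freq grid, complex tapered FFT coefficients and
# the PSD (uV^2/Hz), epochs x bins, for bins 1..floor(n/2) (DC excluded).
.epoch_periodogram <- function(xmat, fs) {
  n <- ncol(xmat)
  w <- .hann(n)
  u <- sum(w^2)
  xw <- sweep(xmat, 2, w, `*`)
  co <- t(apply(xw, 1, stats::fft))
  if (nrow(xmat) == 1L) co <- matrix(co, nrow = 1L)
  keep <- 2:(floor(n / 2) + 1)          # positive frequencies, DC dropped
  co <- co[, keep, drop = FALSE]
  freq <- (keep - 1) * fs / n
  psd <- 2 * (Mod(co)^2) / (fs * u)
  list(freq = freq, coef = co, psd = psd)
}

# indices of frequency bins falling in [low, high), or [low, high] for the
# artifact-rule bands whose upper edge is the filter edge itself
.band_bins <- function(freq, low, high, inclusive_high = FALSE) {
  if (inclusive_high) which(freq >= low & freq <= high)
  else which(freq >= low & freq < high)
}
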