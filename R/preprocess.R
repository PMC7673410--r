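#' Zero-phase band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass filter forward and backward
#' (zero phase, no group delay) to every channel, preserving the bandwidth of
#' interest -- by default 0.5--50 Hz -- while suppressing slow drifts and
#' high-frequency noise outside it. Zero-phase application means 5-s epoch
#' boundaries align before and after filtering.
#'
#' @param rec A [recording()].
#' @param low,high Passband edges in Hz. `high` must be below the Nyquist
#'   frequency `fs/2`.
#' @return The filtered recording (same shape).
#' @export
bandpass <- function(rec, low = 0.5, high = 50) {
  stopifnot(inherits(rec, "wn_recording"))
  if (high >= rec$fs / 2) {
    abort(sprintf("upper passband edge (%g Hz) must be below Nyquist (%g Hz)",
                  high, rec$fs / 2))
  }
  if (low <= 0 || low >= high) abort("need 0 < low < high")
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$samples <- t(apply(rec$samples, 1, function(x) signal::filtfilt(bf, x)))
  rownames(out$samples) <- rec$channel_labels
  out
}

#' Segment a recording into 5-s epochs with per-epoch spectra
#'
#' Splits each channel into consecutive non-overlapping 5-s epochs (a trailing
#' partial epoch is discarded) and computes, per epoch, a Hann-windowed
#' periodogram (0.2 Hz bin spacing at 5 s). Stored alongside are the two
#' artifact-rule band powers (mean PSD over 26--50 Hz and 4--50 Hz), a
#' keep-mask (all `TRUE` until a rejection rule runs) and a rejection-reason
#' grid.
#'
#' @param rec A [recording()] of duration at least 5 s.
#' @param epoch_length Epoch length in seconds (fixed default 5).
#' @return An object of class `wn_epochgrid` with elements `spectra`
#'   (complex array channel x epoch x bin), `psd` (channel x epoch x bin),
#'   `freq`, `emg_power` and `move_power` (channel x epoch), `keep_mask`,
#'   `rejection_reason`.
#' @export
segment_epochs <- function(rec, epoch_length = 5) {
  stopifnot(inherits(rec, "wn_recording"))
  n_samp <- ncol(rec$samples)
  spe <- round(epoch_length * rec$fs)
  n_epochs <- floor(n_samp / spe)
  if (n_epochs < 1) {
    abort(sprintf("recording too short: %.3f s, need at least %g s",
                  n_samp / rec$fs, epoch_length))
  }
  n_ch <- nrow(rec$samples)
  first <- NULL
  spectra <- NULL
  psd <- NULL
  for (ch in seq_len(n_ch)) {
    x <- rec$samples[ch, seq_len(n_epochs * spe)]
    xm <- matrix(x, nrow = n_epochs, ncol = spe, byrow = TRUE)
    pg <- .epoch_periodogram(xm, rec$fs)
    if (is.null(spectra)) {
      first <- pg
      nb <- length(pg$freq)
      spectra <- array(complex(real = 0), dim = c(n_ch, n_epochs, nb))
      psd <- array(0, dim = c(n_ch, n_epochs, nb))
    }
    spectra[ch, , ] <- pg$coef
    psd[ch, , ] <- pg$psd
  }
  freq <- first$freq
  bandmean <- function(low, high) {
    bins <- .band_bins(freq, low, high, inclusive_high = TRUE)
    apply(psd[, , bins, drop = FALSE], c(1, 2), mean)
  }
  structure(
    list(subject_id = rec$subject_id, night = rec$night, fs = rec$fs,
         channel_labels = rec$channel_labels,
         epoch_length = epoch_length, n_epochs = n_epochs, freq = freq,
         spectra = spectra, psd = psd,
         emg_power = bandmean(26, 50),
         move_power = bandmean(4, 50),
         keep_mask = matrix(TRUE, n_ch, n_epochs,
                            dimnames = list(rec$channel_labels, NULL)),
         rejection_reason = matrix("none", n_ch, n_epochs,
                                   dimnames = list(rec$channel_labels, NULL))),
    class = "wn_epochgrid"
  )
}

#' @export
print.wn_epochgrid <- function(x, ...) {
  kept <- mean(x$keep_mask)
  cat(sprintf("<wn_epochgrid> %s night %d: %d channels x %d epochs of %g s, %.1f%% kept\n",
              x$subject_id, x$night, length(x$channel_labels), x$n_epochs,
              x$epoch_length, 100 * kept))
  invisible(x)
}

# centred moving median over `width` epochs, truncated at the edges.
# For even widths the window covers offsets -(width/2 - 1) .. +width/2.
.moving_median <- function(x, width) {
  n <- length(x)
  lo <- ceiling((width - 1) / 2)
  hi <- floor(width / 2)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - lo):min(n, i + hi)])
  }, numeric(1))
}

#' Reject transient high-frequency (muscle) artifact epochs
#'
#' Per channel, marks a 5-s epoch as rejected whenever its 26--50 Hz band
#' power strictly exceeds four times the moving median of that power over a
#' 3-min window (36 epochs) centred on the epoch, truncated at the recording
#' edges. This targets transient EMG bursts riding on the EEG.
#'
#' @param grid A `wn_epochgrid`.
#' @param factor Rejection multiplier (default 4).
#' @param window_epochs Moving-median window length in epochs (default 36,
#'   i.e. 3 minutes of 5-s epochs).
#' @return The grid with updated `keep_mask`/`rejection_reason`.
#' @export
reject_emg <- function(grid, factor = 4, window_epochs = 36) {
  stopifnot(inherits(grid, "wn_epochgrid"))
  for (ch in seq_along(grid$channel_labels)) {
    p <- grid$emg_power[ch, ]
    mm <- .moving_median(p, window_epochs)
    bad <- p > factor * mm
    newly <- bad & grid$keep_mask[ch, ]
    grid$keep_mask[ch, newly] <- FALSE
    grid$rejection_reason[ch, newly] <- "emg"
  }
  grid
}

#' Reject movement / poor-contact artifact epochs
#'
#' Per channel, marks a 5-s epoch as rejected whenever its 4--50 Hz band
#' power strictly exceeds six times that channel's whole-night median. The
#' median is taken over all epochs of the night (including epochs already
#' rejected by the EMG rule), so the rule is idempotent and independent of
#' rule order.
#'
#' @param grid A `wn_epochgrid`.
#' @param factor Rejection multiplier (default 6).
#' @return The grid with updated `keep_mask`/`rejection_reason`.
#' @export
reject_movement <- function(grid, factor = 6) {
  stopifnot(inherits(grid, "wn_epochgrid"))
  for (ch in seq_along(grid$channel_labels)) {
    p <- grid$move_power[ch, ]
    med <- stats::median(p)
    bad <- p > factor * med
    newly <- bad & grid$keep_mask[ch, ]
    grid$keep_mask[ch, newly] <- FALSE
    grid$rejection_reason[ch, newly] <- "movement"
  }
  grid
}

#' Full preprocessing for one recording
#'
#' Band-pass filters, segments into 5-s epochs, then applies the EMG rule
#' followed by the movement rule.
#'
#' @inheritParams bandpass
#' @return A `wn_epochgrid` with artifact epochs masked.
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 50) {
  rec %>% bandpass(low, high) %>% segment_epochs() %>%
    reject_emg() %>% reject_movement()
}

#' Per-channel rejection summary
#'
#' @param grid A `wn_epochgrid`.
#' @return A tibble with per-channel kept/rejected epoch counts and rates.
#' @export
rejection_summary <- function(grid) {
  stopifnot(inherits(grid, "wn_epochgrid"))
  tibble(
    subject_id = grid$subject_id,
    night = grid$night,
    channel = grid$channel_labels,
    n_epochs = grid$n_epochs,
    n_kept = rowSums(grid$keep_mask),
    n_emg = rowSums(grid$rejection_reason == "emg"),
    n_movement = rowSums(grid$rejection_reason == "movement")
  ) %>% mutate(frac_rejected = 1 - .data$n_kept / .data$n_epochs)
}
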