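#' Per-epoch log band power for one channel
#'
#' Natural log of the mean power spectral density over a band's frequency
#' bins, one value per artifact-free epoch of the given channel. Bands are
#' half-open `[low, high)`.
#'
#' @param grid A `wn_epochgrid`.
#' @param channel Channel label.
#' @param band Band code (see [eeg_bands()]), or a numeric `c(low, high)`.
#' @return Numeric vector of log band powers over kept epochs.
#' @export
epoch_log_band_power <- function(grid, channel, band) {
  stopifnot(inherits(grid, "wn_epochgrid"))
  ch <- match(channel, grid$channel_labels)
  if (is.na(ch)) abort(sprintf("channel '%s' not present", channel))
  lh <- .band_range(band)
  bins <- .band_bins(grid$freq, lh[1], lh[2])
  kept <- which(grid$keep_mask[ch, ])
  if (length(kept) == 0) {
    abort(sprintf("no artifact-free epochs for channel '%s'", channel))
  }
  bp <- apply(grid$psd[ch, kept, bins, drop = FALSE], 2, mean)
  log(bp)
}

.band_range <- function(band) {
  if (is.numeric(band)) {
    stopifnot(length(band) == 2, band[1] < band[2])
    return(band)
  }
  b <- eeg_bands()
  i <- match(band, b$band)
  if (is.na(i)) abort(sprintf("unknown band '%s'", band))
  c(b$low[i], b$high[i])
}

#' Whole-night mean log power (LP)
#'
#' The LP feature: mean over artifact-free epochs of the log band power.
#'
#' @param series Per-epoch log band power series.
#' @return Scalar LP, or `NA` for an empty series.
#' @export
lp_feature <- function(series) {
  if (length(series) == 0) return(NA_real_)
  mean(series)
}

#' Whole-night coefficient of variation of log power (LCV)
#'
#' The LCV feature: ratio of the standard deviation (denominator n - 1) to
#' the mean of the per-epoch log band power.
#'
#' @param series Per-epoch log band power series.
#' @return Scalar LCV, or `NA` if the series is empty or its mean is 0.
#' @export
lcv_feature <- function(series) {
  if (length(series) == 0) return(NA_real_)
  m <- mean(series)
  if (m == 0) return(NA_real_)
  stats::sd(series) / m
}

# core WPLI ratio from imaginary parts of cross-spectral values
.wpli_ratio <- function(im) {
  denom <- sum(abs(im))
  if (denom == 0) return(NA_real_)
  abs(sum(im)) / denom
}

#' Weighted phase lag index between two channels
#'
#' Phase synchrony in `[0, 1]` (1 perfect synchrony, 0 none) computed from
#' the imaginary part of the cross-spectrum, which makes it insensitive to
#' zero-lag (volume-conducted) coupling:
#' \deqn{W = |\sum_k \mathrm{Im}\, S_{ij}(k)| / \sum_k |\mathrm{Im}\, S_{ij}(k)|}
#' where \eqn{S_{ij}(k)} runs over all frequency bins inside the band across
#' all epochs kept in *both* channels' masks (one pooled ratio, not a per-bin
#' average). Symmetric in channel order and invariant to per-channel
#' amplitude scaling.
#'
#' @param grid A `wn_epochgrid`.
#' @param channel_i,channel_j Channel labels.
#' @param band Band code or numeric `c(low, high)`.
#' @return W in `[0, 1]`, or `NA` if no jointly kept epochs or the
#'   denominator is zero.
#' @export
wpli <- function(grid, channel_i, channel_j, band) {
  stopifnot(inherits(grid, "wn_epochgrid"))
  ci <- match(channel_i, grid$channel_labels)
  cj <- match(channel_j, grid$channel_labels)
  if (is.na(ci) || is.na(cj)) abort("channel not present")
  lh <- .band_range(band)
  bins <- .band_bins(grid$freq, lh[1], lh[2])
  kept <- which(grid$keep_mask[ci, ] & grid$keep_mask[cj, ])
  if (length(kept) == 0) return(NA_real_)
  cross <- grid$spectra[ci, kept, bins] * Conj(grid$spectra[cj, kept, bins])
  .wpli_ratio(Im(cross))
}

#' Assemble the whole-night feature table
#'
#' Computes every LP, LCV and W feature for a set of preprocessed
#' subject-nights and joins them to subject metadata. For the standard 10
#' channels and 12 bands this is 120 + 120 + 540 = 780 features per
#' subject-night; in general `C*B` LP + `C*B` LCV + `C(C-1)/2*B` W features
#' for `C` channels and `B` bands.
#'
#' @param grids List of `wn_epochgrid` objects (one per subject-night).
#' @param meta Tibble with columns `subject_id`, `group`, `age`, `split`.
#' @param channels Channels required in every grid (default all ten).
#' @param bands Band codes (default all twelve).
#' @return A feature table: one row per subject-night with metadata columns
#'   `subject_id`, `night`, `group`, `age`, `split` followed by the named
#'   feature columns.
#' @export
assemble_features <- function(grids, meta, channels = eeg_channels(),
                              bands = eeg_bands()$band) {
  stopifnot(is.list(grids), length(grids) >= 1)
  for (g in grids) {
    missing_ch <- setdiff(channels, g$channel_labels)
    if (length(missing_ch) > 0) {
      abort(sprintf("grid %s night %d is missing channel(s): %s",
                    g$subject_id, g$night, paste(missing_ch, collapse = ", ")))
    }
  }
  fn <- feature_names(channels, bands)
  pairs <- if (length(channels) >= 2) utils::combn(sort(channels), 2) else NULL
  rows <- purrr::map_dfr(grids, function(g) {
    vals <- numeric(0)
    for (ch in channels) {
      for (b in bands) {
        series <- epoch_log_band_power(g, ch, b)
        vals[paste("LP", ch, b, sep = "-")] <- lp_feature(series)
        vals[paste("LCV", ch, b, sep = "-")] <- lcv_feature(series)
      }
    }
    if (!is.null(pairs)) {
      for (k in seq_len(ncol(pairs))) {
        for (b in bands) {
          vals[paste("W", pairs[1, k], pairs[2, k], b, sep = "-")] <-
            wpli(g, pairs[1, k], pairs[2, k], b)
        }
      }
    }
    dplyr::bind_cols(tibble(subject_id = g$subject_id, night = g$night),
                     as_tibble(as.list(vals[fn])))
  })
  out <- dplyr::left_join(rows, meta[, c("subject_id", "group", "age", "split")],
                          by = "subject_id")
  dplyr::select(out, dplyr::all_of(.meta_cols), dplyr::all_of(fn))
}
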