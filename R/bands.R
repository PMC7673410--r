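#' The twelve analysis frequency bands
#'
#' Returns the fixed set of twelve contiguous frequency bands spanning
#' 0.5--40 Hz over which every whole-night feature is computed: slow
#' oscillations (SO, 0.5--1 Hz), low/high delta (Ld 1--2, Hd 2--4), low/high
#' theta (Lt 4--6, Ht 6--8), low/high alpha (La 8--10, Ha 10--12), low/high
#' sigma (Ls 12--14, Hs 14--16), low/high beta (Lb 16--24, Hb 24--32) and low
#' gamma (Lg 32--40).
#'
#' Band edges are half-open `[low, high)`: a spectral bin at exactly 10 Hz
#' belongs to the high-alpha band, not low-alpha, so the bands partition the
#' frequency axis without overlap. ASCII band codes are used in feature names;
#' the conventional Greek labels are provided for display.
#'
#' @return A tibble with columns `band` (ASCII code used in feature names),
#'   `low`, `high` (Hz) and `label` (Greek display label).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band  = c("SO", "Ld", "Hd", "Lt", "Ht", "La",
              "Ha", "Ls", "Hs", "Lb", "Hb", "Lg"),
    low   = c(0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 24, 32),
    high  = c(1, 2, 4, 6, 8, 10, 12, 14, 16, 24, 32, 40),
    label = c("SO", "Lδ", "Hδ", "Lθ", "Hθ", "Lα",
              "Hα", "Lσ", "Hσ", "Lβ", "Hβ", "Lγ")
  )
}

#' The ten standard analysis channels
#'
#' The ten most commonly used scalp EEG channels, covering frontal, central,
#' temporal, parietal and occipital regions, in montage order.
#'
#' @return Character vector of channel labels.
#' @export
eeg_channels <- function() {
  c("F3", "F4", "C3", "C4", "T3", "T4", "P3", "P4", "O1", "O2")
}

#' Enumerate whole-night feature names
#'
#' Builds the full set of feature names for a channel set and band set under
#' the grammar `<LP|LCV|W>-<channel[-channel2]>-<band>`, e.g. `LP-C3-Ld` for
#' the mean log power of channel C3 in the low-delta band, or `W-C3-F3-Hb`
#' for the weighted phase lag index between C3 and F3 in high beta. Synchrony
#' (W) features enumerate the `C(C-1)/2` unordered channel pairs with the
#' lexicographically first channel named first. For the default 10 channels
#' and 12 bands this yields 120 LP + 120 LCV + 540 W = 780 names.
#'
#' @param channels Character vector of channel labels.
#' @param bands Character vector of band codes (default the 12 standard bands).
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_names()) # 780
feature_names <- function(channels = eeg_channels(), bands = eeg_bands()$band) {
  stopifnot(length(channels) >= 1, !anyDuplicated(channels))
  per_ch <- function(type) {
    as.vector(t(outer(channels, bands, function(ch, b) paste(type, ch, b, sep = "-"))))
  }
  w <- character(0)
  if (length(channels) >= 2) {
    pairs <- utils::combn(sort(channels), 2)
    w <- as.vector(apply(pairs, 2, function(p) paste("W", p[1], p[2], bands, sep = "-")))
  }
  c(per_ch("LP"), per_ch("LCV"), w)
}

#' Parse feature names into their components
#'
#' Inverts the feature-name grammar: `parse_feature_names(feature_names())`
#' round-trips exactly.
#'
#' @param x Character vector of feature names.
#' @return A tibble with columns `name`, `type` (LP/LCV/W), `channel`,
#'   `channel2` (`NA` for LP/LCV) and `band`.
#' @export
parse_feature_names <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  bad <- !lengths(parts) %in% c(3L, 4L)
  if (any(bad)) {
    abort(paste0("Malformed feature name(s): ", paste(x[bad], collapse = ", ")))
  }
  out <- purrr::map_dfr(parts, function(p) {
    if (length(p) == 3L) {
      tibble(type = p[1], channel = p[2], channel2 = NA_character_, band = p[3])
    } else {
      tibble(type = p[1], channel = p[2], channel2 = p[3], band = p[4])
    }
  })
  bad_type <- !(out$type %in% c("LP", "LCV", "W")) |
    (out$type == "W") != !is.na(out$channel2)
  if (any(bad_type)) {
    abort(paste0("Malformed feature name(s): ", paste(x[bad_type], collapse = ", ")))
  }
  dplyr::bind_cols(tibble(name = x), out)
}

# columns of a feature table that are metadata, not features
.meta_cols <- c("subject_id", "night", "group", "age", "split")

# feature columns of a feature table, in stored order
.feature_cols <- function(tbl) setdiff(names(tbl), .meta_cols)

.w_cols <- function(tbl) {
  fc <- .feature_cols(tbl)
  fc[startsWith(fc, "W-")]
}
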