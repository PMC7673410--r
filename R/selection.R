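#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic divided
#' by `n_pos * n_neg`, with tied value pairs counted 1/2. Equals the
#' probability that a random positive-class value exceeds a random
#' negative-class value, and is invariant under strictly monotone transforms
#' of the values.
#'
#' @param values Numeric scores.
#' @param labels Logical or factor; `TRUE` / level `"PTSD"` marks the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' rank_auc(c(3, 4, 1, 2, 3.5), c(TRUE, TRUE, FALSE, FALSE, FALSE)) # 5/6
rank_auc <- function(values, labels) {
  pos <- .as_positive(labels)
  m <- sum(pos); k <- sum(!pos)
  if (m == 0 || k == 0) abort("both classes must be present to compute an AUC")
  r <- rank(values)               # midranks handle ties
  (sum(r[pos]) - m * (m + 1) / 2) / (m * k)
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels == "PTSD"
}

#' DeLong 95% confidence interval for an AUC
#'
#' Variance of the empirical AUC from DeLong's placement decomposition:
#' per-observation placements `V10` (positives) and `V01` (negatives) give
#' `var(AUC) = var(V10)/m + var(V01)/k`; the normal-approximation interval is
#' clipped to `[0, 1]`. When the variance degenerates to zero (AUC exactly 0
#' or 1, or all values tied within class placements) the interval collapses
#' to the point estimate.
#'
#' @inheritParams rank_auc
#' @param level Confidence level (default 0.95).
#' @param warn Warn when the interval degenerates to a point (default TRUE).
#' @return A named list: `auc`, `lb`, `ub`, `se`.
#' @export
auc_ci <- function(values, labels, level = 0.95, warn = TRUE) {
  pos <- .as_positive(labels)
  x <- values[pos]; y <- values[!pos]
  m <- length(x); k <- length(y)
  if (m < 2 || k < 2) abort("need at least 2 observations per class for a CI")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- 1 - colMeans(psi)          # placements oriented so mean(1 - v01) = auc
  a <- mean(v10)
  s2 <- stats::var(v10) / m + stats::var(1 - v01) / k
  if (s2 == 0) {
    if (warn) warn("degenerate AUC variance; CI collapsed to the point estimate")
    return(list(auc = a, lb = a, ub = a, se = 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(s2)
  list(auc = a, lb = max(0, a - z * se), ub = min(1, a + z * se), se = se)
}

#' Per-night univariate AUC screen
#'
#' Fig.-style step 4 of the workflow: on training subjects only, computes
#' each feature's AUC and 95% CI separately for night 1 and night 2, and
#' selects the features whose CI *lower bound* strictly exceeds 0.5 on
#' **each** of the two nights -- a two-night guard against chance
#' associations. Because the AUC is direction-sensitive and every feature is
#' reported with AUC >= 0.5, each feature's orientation (sign) is fixed from
#' training night 1 and reused for night 2 and the concatenated-nights AUC;
#' selection and downstream stages always see the oriented feature. The
#' concatenated AUC treats each training subject's two nights as two
#' observations with the same label.
#'
#' @param tbl A conditioned feature table (train + test rows; two nights).
#' @param level CI level (default 0.95).
#' @return A `wn_selection` tibble with one row per feature: `feature`,
#'   `orientation` (+1/-1), per-night `auc`/`ci_lb`/`ci_ub`, `auc_concat`,
#'   `selected`.
#' @export
select_features <- function(tbl, level = 0.95) {
  fc <- .feature_cols(tbl)
  tr <- dplyr::filter(tbl, .data$split == "train")
  if (length(unique(tr$night)) < 2) abort("training data must contain two nights")
  n1 <- dplyr::filter(tr, .data$night == 1)
  n2 <- dplyr::filter(tr, .data$night == 2)
  pos1 <- .as_positive(n1$group); pos2 <- .as_positive(n2$group)
  post <- .as_positive(tr$group)
  rows <- purrr::map_dfr(fc, function(f) {
    orient <- if (rank_auc(n1[[f]], pos1) >= 0.5) 1 else -1
    c1 <- auc_ci(orient * n1[[f]], pos1, level, warn = FALSE)
    c2 <- auc_ci(orient * n2[[f]], pos2, level, warn = FALSE)
    tibble(feature = f, orientation = orient,
           auc_night1 = c1$auc, ci_lb_night1 = c1$lb, ci_ub_night1 = c1$ub,
           auc_night2 = c2$auc, ci_lb_night2 = c2$lb, ci_ub_night2 = c2$ub,
           auc_concat = rank_auc(orient * tr[[f]], post),
           selected = c1$lb > 0.5 && c2$lb > 0.5)
  })
  class(rows) <- c("wn_selection", class(rows))
  rows
}

#' Apply feature orientations from a selection record
#'
#' Multiplies each feature column by its fixed orientation so that larger
#' oriented values always point toward the positive class on training
#' night 1.
#'
#' @param tbl A feature table.
#' @param records A `wn_selection` from [select_features()].
#' @return The oriented feature table (columns restricted to `records`).
#' @export
orient_features <- function(tbl, records) {
  keep <- records$feature
  out <- dplyr::select(tbl, dplyr::all_of(.meta_cols), dplyr::all_of(keep))
  for (i in seq_along(keep)) {
    if (records$orientation[i] < 0) out[[keep[i]]] <- -out[[keep[i]]]
  }
  out
}
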