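#' Log-transform synchrony features
#'
#' Replaces every weighted-phase-lag-index (`W-`) column of a feature table
#' by its natural log, flooring at `eps` so that W = 0 maps to `log(eps)`
#' rather than `-Inf`. This puts the synchrony features on a log scale
#' comparable to the LP/LCV features and reduces heteroscedasticity before
#' classifier development. LP and LCV columns are untouched.
#'
#' @param tbl A feature table.
#' @param eps Floor applied before the log (default `1e-6`, below any
#'   attainable WPLI resolution at realistic epoch counts).
#' @return The transformed feature table.
#' @export
log_transform_synchrony <- function(tbl, eps = 1e-6) {
  wc <- .w_cols(tbl)
  if (length(wc) > 0) {
    wvals <- as.matrix(tbl[, wc])
    if (any(wvals < 0 | wvals > 1, na.rm = TRUE)) {
      abort("synchrony (W) features must lie in [0, 1] before log transform")
    }
    tbl[, wc] <- log(pmax(wvals, eps))
  }
  tbl
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement (not just correlation) between paired measurements:
#' \deqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with variances and covariance using denominator n. Unlike Pearson's r,
#' the CCC is penalised by location and scale shifts, so it is 1 only when
#' `y = x` exactly. Here it quantifies night-1 vs night-2 test-retest
#' consistency of a feature across subjects.
#'
#' @param x,y Paired numeric vectors (e.g. night-1 and night-2 values).
#' @return CCC in `[-1, 1]`; 1 if both vectors are identical constants; `NA`
#'   if the denominator is zero otherwise.
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4)) # 4/7
ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(if (all(x == y)) 1 else NA_real_)
  2 * sxy / denom
}

#' Two-night concordance filter
#'
#' Computes, for every feature, Lin's CCC between the night-1 and night-2
#' values across *training* subjects, and flags the feature as retained iff
#' CCC strictly exceeds `threshold`. Test subjects never influence the
#' filter. Subjects missing either night are dropped pairwise.
#'
#' @param tbl A feature table with two nights per training subject.
#' @param threshold Retention threshold (default 0.7, strict).
#' @return A tibble with columns `feature`, `ccc`, `retained`.
#' @export
concordance_filter <- function(tbl, threshold = 0.7) {
  fc <- .feature_cols(tbl)
  tr <- dplyr::filter(tbl, .data$split == "train")
  n1 <- dplyr::filter(tr, .data$night == 1) %>% arrange(.data$subject_id)
  n2 <- dplyr::filter(tr, .data$night == 2) %>% arrange(.data$subject_id)
  common <- intersect(n1$subject_id, n2$subject_id)
  if (length(common) < 3) abort("need at least 3 training subjects with both nights")
  n1 <- n1[match(common, n1$subject_id), ]
  n2 <- n2[match(common, n2$subject_id), ]
  cccs <- vapply(fc, function(f) ccc(n1[[f]], n2[[f]]), numeric(1))
  tibble(feature = fc, ccc = unname(cccs),
         retained = !is.na(cccs) & cccs > threshold)
}

#' Apply a concordance filter to a feature table
#'
#' Drops the feature columns not retained by [concordance_filter()].
#'
#' @param tbl A feature table.
#' @param report A [concordance_filter()] report (computed from `tbl` if
#'   missing).
#' @return The feature table restricted to retained features.
#' @export
apply_concordance_filter <- function(tbl, report = concordance_filter(tbl)) {
  keep <- report$feature[report$retained]
  dplyr::select(tbl, dplyr::all_of(.meta_cols), dplyr::all_of(keep))
}

#' Screen for and remove age effects
#'
#' For each feature, computes Pearson's correlation with age on the
#' *control training* subject-nights only (both nights pooled; using
#' controls avoids regressing out disorder-related variation). Features
#' significantly correlated with age (two-sided p < `alpha`, exact t
#' transform, no multiplicity correction) are corrected for **all** subjects
#' and nights by removing the fitted linear age trend, centred at the mean
#' age of control training subjects so the feature scale is preserved:
#' `value - b * (age - mean_age_ctrl_train)`. Features with p >= `alpha`
#' pass through unchanged.
#'
#' @param tbl A feature table.
#' @param alpha Screening significance level (default 0.05).
#' @return The corrected feature table, with the screening report attached as
#'   attribute `"age_report"` (columns `feature`, `age_r`, `age_p`,
#'   `age_slope`, `corrected`); retrieve it with [age_report()].
#' @export
age_screen_and_correct <- function(tbl, alpha = 0.05) {
  fc <- .feature_cols(tbl)
  ctrl <- dplyr::filter(tbl, .data$split == "train", .data$group == "control")
  if (nrow(ctrl) < 3 || length(unique(ctrl$subject_id)) < 3) {
    abort("need at least 3 control training subjects for age screening")
  }
  if (stats::sd(ctrl$age) == 0) {
    warn("no age variance among control training subjects; age screening skipped")
    attr(tbl, "age_report") <- tibble(feature = fc, age_r = NA_real_,
                                      age_p = NA_real_, age_slope = 0,
                                      corrected = FALSE)
    return(tbl)
  }
  abar <- mean(ctrl$age)
  report <- purrr::map_dfr(fc, function(f) {
    ct <- stats::cor.test(ctrl[[f]], ctrl$age, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
    if (!is.na(p) && p < alpha) {
      b <- unname(coef(stats::lm(ctrl[[f]] ~ ctrl$age))[2])
      tibble(feature = f, age_r = r, age_p = p, age_slope = b, corrected = TRUE)
    } else {
      tibble(feature = f, age_r = r, age_p = p, age_slope = 0, corrected = FALSE)
    }
  })
  for (i in which(report$corrected)) {
    f <- report$feature[i]
    tbl[[f]] <- tbl[[f]] - report$age_slope[i] * (tbl$age - abar)
  }
  attr(tbl, "age_report") <- report
  tbl
}

#' Retrieve the age-screening report from a corrected table
#'
#' @param tbl A table returned by [age_screen_and_correct()].
#' @return The report tibble.
#' @export
age_report <- function(tbl) {
  rep <- attr(tbl, "age_report")
  if (is.null(rep)) abort("no age report attached; run age_screen_and_correct() first")
  rep
}
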