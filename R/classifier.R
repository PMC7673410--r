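# Ridge-penalised logistic regression by Newton/IRLS.
# Minimises -loglik + (lambda/2) * sum(beta^2) (intercept unpenalised).
# The weak default penalty (lambda = 1/(100 n), set by the caller) exists for
# numerical stability under (quasi-)separation, not for shrinkage; the fit is
# deterministic given the data.
.ridge_logistic <- function(X, y, lambda, max_iter = 200, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- c(0, rep(lambda, p - 1))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X1, y - mu)) - pen * beta
    H <- crossprod(X1 * w, X1) + diag(pen, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol && max(abs(step)) < tol) break
  }
  list(beta = beta, converged = it < max_iter || max(abs(grad)) < 1e-6,
       iterations = it)
}

#' Fit the whole-night logistic classifier
#'
#' Fits a logistic regression of group (PTSD vs control) on the given
#' features using the *combined training data from both nights* (each
#' subject-night row is one observation). Features are standardised by their
#' training mean and SD; a weak L2 ridge penalty of strength `1/(100 n)`
#' keeps the maximum-likelihood fit finite and deterministic under perfect
#' separation (a warning is logged when separation is detected).
#'
#' @param tbl A feature table (oriented, conditioned); only `split ==
#'   "train"` rows are used.
#' @param features Character vector of feature columns to include.
#' @param lambda Ridge penalty; default `1/(100 n)` where n is the number of
#'   training observations.
#' @return A `wn_classifier`: feature names, standardisation constants,
#'   standardised-scale coefficients and intercept, and an empty threshold
#'   map (see [threshold_for_sensitivity()]).
#' @export
fit_logistic <- function(tbl, features, lambda = NULL) {
  tr <- dplyr::filter(tbl, .data$split == "train")
  if (nrow(tr) == 0) abort("no training rows")
  y <- as.numeric(.as_positive(tr$group))
  if (length(unique(y)) < 2) abort("both classes must be present in training data")
  X <- as.matrix(tr[, features, drop = FALSE])
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) {
    abort(paste0("degenerate (constant) feature(s): ",
                 paste(features[sdev == 0], collapse = ", ")))
  }
  Xs <- scale(X, center = mu, scale = sdev)
  n <- nrow(Xs)
  if (is.null(lambda)) lambda <- 1 / (100 * n)
  fit <- .ridge_logistic(Xs, y, lambda)
  eta <- drop(cbind(1, Xs) %*% fit$beta)
  if (min(eta[y == 1]) > max(eta[y == 0])) {
    warn("training classes are separated; coefficients bounded only by the ridge penalty")
  }
  structure(
    list(feature_names = features,
         coefficients = stats::setNames(fit$beta[-1], features),
         intercept = fit$beta[1],
         standardization = list(mean = mu, sd = sdev),
         lambda = lambda, n_train = n, converged = fit$converged,
         thresholds = numeric(0)),
    class = "wn_classifier"
  )
}

#' @export
print.wn_classifier <- function(x, ...) {
  cat(sprintf("<wn_classifier> logistic model on %d feature(s), n_train = %d\n",
              length(x$feature_names), x$n_train))
  print(round(x$coefficients, 4))
  if (length(x$thresholds)) {
    cat("thresholds:", paste(sprintf("%s -> %.4f", names(x$thresholds),
                                     x$thresholds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted PTSD probabilities
#'
#' @param object A `wn_classifier`.
#' @param newdata A feature table containing the model's features.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.wn_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Xs <- scale(X, center = object$standardization$mean,
              scale = object$standardization$sd)
  stats::plogis(drop(object$intercept + Xs %*% object$coefficients))
}

# subject-level stratified fold assignment: both nights of a subject share a
# fold; folds balance the group ratio.
.make_folds <- function(subjects, groups, folds, seed, max_retries = 20) {
  uniq <- !duplicated(subjects)
  sid <- subjects[uniq]
  grp <- .as_positive(groups[uniq])
  if (min(sum(grp), sum(!grp)) < folds) {
    abort(sprintf(
      "need at least %d subjects per class for %d-fold CV (have %d PTSD, %d control)",
      folds, folds, sum(grp), sum(!grp)))
  }
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    fold_of <- integer(length(sid))
    for (g in c(TRUE, FALSE)) {
      idx <- sample(which(grp == g))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(grp[fold_of == f])) == 2
    }, logical(1)))
    if (ok) return(fold_of[match(subjects, sid)])
  }
  abort("could not build folds with both classes present in every fold")
}

# backward-elimination path: at each size, drop the feature with the
# smallest absolute standardised coefficient; returns the nested sets
.rfe_path <- function(tbl, features) {
  sets <- list()
  current <- features
  while (length(current) >= 1) {
    sets[[length(current)]] <- current
    if (length(current) == 1) break
    fit <- fit_logistic(tbl, current)
    current <- setdiff(current, names(which.min(abs(fit$coefficients))))
  }
  sets
}

#' Recursive feature elimination with cross-validated logistic regression
#'
#' Determines the smallest feature set that preserves cross-validated
#' discrimination. Folds are stratified by group, keep both nights of a
#' subject together (splitting a subject across folds would leak
#' within-subject information), and are assigned from `seed`. Inside each
#' fold, a full backward-elimination path is built on the fold's training
#' portion alone -- at every size the feature with the smallest absolute
#' standardised coefficient is dropped -- and each size is scored by the AUC
#' of that fold's size-`s` model on the held-out portion. Running the
#' elimination inside the folds matters: ranking features on the full
#' training data would let chance-associated features validate on held-out
#' subjects drawn from the same sample.
#'
#' Because the ridge-stabilised fit never produces exactly-zero
#' coefficients, "the smallest set with non-zero coefficients" is
#' operationalised by a fold-paired one-standard-error rule: the chosen size
#' is the smallest whose fold-wise CV AUCs are statistically
#' indistinguishable from the best size's
#' (`mean(auc_best - auc_s) <= se(auc_best - auc_s)`, differences within
#' matched folds). The returned feature set is the backward-elimination set
#' of that size on the full training data.
#'
#' @param tbl An oriented feature table; only training rows are used
#'   (both nights, concatenated).
#' @param features Candidate feature names.
#' @param folds Number of CV folds (default 6).
#' @param seed Seed for fold assignment.
#' @return A list: `features` (the selected minimal set), `path` (tibble of
#'   set size, mean and SE of CV AUC, and the full-data elimination set),
#'   `folds`.
#' @export
rfe_cv <- function(tbl, features, folds = 6, seed = 1L) {
  tr <- dplyr::filter(tbl, .data$split == "train")
  y <- .as_positive(tr$group)
  fold_of <- .make_folds(tr$subject_id, tr$group, folds, seed)
  sizes <- seq_along(features)
  # per-fold elimination paths and per-size held-out AUCs
  fold_aucs <- matrix(NA_real_, length(features), folds)
  for (f in seq_len(folds)) {
    hold <- fold_of == f
    path_f <- .rfe_path(tr[!hold, ], features)
    for (s in sizes) {
      fit <- fit_logistic(tr[!hold, ], path_f[[s]])
      fold_aucs[s, f] <- rank_auc(predict(fit, tr[hold, ]), y[hold])
    }
  }
  full_sets <- .rfe_path(tr, features)
  path <- tibble(
    size = sizes,
    cv_auc = rowMeans(fold_aucs),
    cv_se = apply(fold_aucs, 1, stats::sd) / sqrt(folds),
    features = vapply(full_sets, paste, character(1), collapse = ","))
  best_size <- path$size[which.max(path$cv_auc)]
  eligible <- vapply(sizes, function(s) {
    d <- fold_aucs[best_size, ] - fold_aucs[s, ]
    all(d == 0) || mean(d) <= stats::sd(d) / sqrt(folds)
  }, logical(1))
  chosen <- min(sizes[eligible])
  list(features = full_sets[[chosen]], path = path, folds = folds)
}

#' Probability threshold achieving a target training sensitivity
#'
#' Scans the training ROC for the *largest* probability cutoff whose
#' training-set sensitivity (predicting PTSD when probability >= cutoff) is
#' at least `target_sens`; the achieved sensitivity is reported alongside.
#' Target 0 returns cutoff 1. By ROC monotonicity the cutoff is
#' non-increasing in the target.
#'
#' @param model A `wn_classifier`.
#' @param tbl Feature table; training rows are used.
#' @param target_sens Target sensitivity in `[0, 1]`.
#' @return A list: `cutoff`, `achieved_sens`.
#' @export
threshold_for_sensitivity <- function(model, tbl, target_sens) {
  if (target_sens < 0 || target_sens > 1) abort("`target_sens` must be in [0, 1]")
  tr <- dplyr::filter(tbl, .data$split == "train")
  p <- predict(model, tr)
  ppos <- sort(p[.as_positive(tr$group)], decreasing = TRUE)
  m <- length(ppos)
  if (m == 0) abort("no positive-class training observations")
  if (target_sens == 0) return(list(cutoff = 1, achieved_sens = mean(ppos >= 1)))
  k <- ceiling(target_sens * m)
  cutoff <- ppos[k]
  list(cutoff = cutoff, achieved_sens = mean(ppos >= cutoff))
}

#' Prevalence-adjusted positive predictive value
#'
#' Re-expresses the PPV as an explicit function of sensitivity, specificity
#' and an assumed population prevalence `pi`:
#' \deqn{PPV = \frac{sens \cdot \pi}{sens \cdot \pi + (1 - spec)(1 - \pi)}}
#' so that a model evaluated on a case-enriched study sample can be reported
#' at the prevalence of the target population (0.15 for combat-exposed
#' Veteran men). Strictly increasing in each argument where defined.
#'
#' @param sens,spec Sensitivity and specificity in `[0, 1]` (vectorised).
#' @param prevalence Assumed population prevalence in `[0, 1]`.
#' @return Adjusted PPV in `[0, 1]`; `NA` where the denominator is 0.
#' @export
#' @examples
#' adjusted_ppv(0.85, 0.67, 0.15) # ~0.31
adjusted_ppv <- function(sens, spec, prevalence = 0.15) {
  stopifnot(all(sens >= 0 & sens <= 1, na.rm = TRUE),
            all(spec >= 0 & spec <= 1, na.rm = TRUE),
            prevalence >= 0, prevalence <= 1)
  num <- sens * prevalence
  den <- num + (1 - spec) * (1 - prevalence)
  ifelse(den == 0, NA_real_, num / den)
}

#' Evaluate a fitted classifier on one data slice
#'
#' Applies the model at a probability cutoff (positive iff probability >=
#' cutoff) to one slice of a feature table -- e.g. one night of the test set
#' -- and reports sensitivity, specificity, AUC with DeLong CI, and the
#' prevalence-adjusted PPV.
#'
#' @param model A `wn_classifier`.
#' @param tbl A feature-table slice with known labels.
#' @param cutoff Probability cutoff.
#' @param prevalence Population prevalence for the adjusted PPV.
#' @return A one-row tibble of metrics.
#' @export
evaluate_classifier <- function(model, tbl, cutoff, prevalence = 0.15) {
  p <- predict(model, tbl)
  pos <- .as_positive(tbl$group)
  pred <- p >= cutoff
  sens <- if (any(pos)) mean(pred[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!pred[!pos]) else NA_real_
  if (any(pos) && any(!pos) && sum(pos) >= 2 && sum(!pos) >= 2) {
    ci <- auc_ci(p, pos, warn = FALSE)
    auc <- ci$auc; lb <- ci$lb; ub <- ci$ub
  } else if (any(pos) && any(!pos)) {
    auc <- rank_auc(p, pos); lb <- NA_real_; ub <- NA_real_
  } else {
    auc <- NA_real_; lb <- NA_real_; ub <- NA_real_
  }
  tibble(n = nrow(tbl), n_pos = sum(pos), cutoff = cutoff,
         sensitivity = sens, specificity = spec,
         auc = auc, auc_lb = lb, auc_ub = ub,
         prevalence = prevalence,
         adjusted_ppv = adjusted_ppv(sens, spec, prevalence))
}
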