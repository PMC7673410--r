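#' Sample distance correlation
#'
#' Székely's distance correlation (V-statistic form): Euclidean distance
#' matrices of `x` and `y` are double-centred, `dCov^2` is the mean of their
#' elementwise product, and `dCor = dCov / sqrt(dVar_x dVar_y)`. Ranges from
#' 0 (population value iff independent) to 1 (perfect linear relation);
#' defined as 0 when either distance variance is 0 (constant input).
#' Invariant under affine transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length (n >= 4 recommended).
#' @return dCor in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  A <- .dcenter(x)
  B <- .dcenter(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx == 0 || dvy == 0) return(0)
  dcov2 <- mean(A * B)
  sqrt(max(dcov2, 0)) / (dvx * dvy)^(1 / 4)
}

.dcenter <- function(x) {
  a <- abs(outer(x, x, `-`))
  a - outer(rowMeans(a), rep(1, length(x))) -
    outer(rep(1, length(x)), colMeans(a)) + mean(a)
}

#' Pairwise distance-correlation matrix
#'
#' @param mat Numeric matrix, observations x features.
#' @return Symmetric feature x feature dCor matrix (unit diagonal for
#'   non-constant features).
#' @export
dcor_matrix <- function(mat) {
  p <- ncol(mat)
  centred <- lapply(seq_len(p), function(j) .dcenter(mat[, j]))
  dvar <- vapply(centred, function(A) mean(A * A), numeric(1))
  out <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)[-seq_len(i)]) {
      if (dvar[i] == 0 || dvar[j] == 0) {
        out[i, j] <- out[j, i] <- 0
      } else {
        dcov2 <- mean(centred[[i]] * centred[[j]])
        out[i, j] <- out[j, i] <- sqrt(max(dcov2, 0)) / (dvar[i] * dvar[j])^(1 / 4)
      }
    }
  }
  if (any(dvar == 0)) {
    dg <- diag(out)
    dg[dvar == 0] <- 0
    diag(out) <- dg
  }
  dimnames(out) <- list(colnames(mat), colnames(mat))
  out
}

#' Cluster features by distance correlation
#'
#' Groups redundant features: agglomerative clustering with dissimilarity
#' `1 - dCor` and *complete* linkage, cutting the dendrogram just below
#' height `1 - threshold` so that every within-cluster pair has dCor
#' strictly above the threshold (complete linkage is the only standard
#' linkage with this pairwise guarantee). Singleton clusters become
#' "independent" features.
#'
#' @param mat Observations x features matrix (concatenated training nights),
#'   or a precomputed dCor matrix (square, symmetric, unit-ish diagonal).
#' @param threshold dCor above which features are considered redundant
#'   (default 0.7, strict).
#' @return A `wn_clusters` list: `dcor` (matrix), `clusters` (list of
#'   feature-name vectors, size >= 2), `independents` (character vector),
#'   `threshold`.
#' @export
cluster_features <- function(mat, threshold = 0.7) {
  mat <- as.matrix(mat)
  dc <- if (nrow(mat) == ncol(mat) &&
            isTRUE(all.equal(unname(mat), unname(t(mat)))) &&
            all(mat >= 0 & mat <= 1 + 1e-12)) mat else dcor_matrix(mat)
  fnames <- colnames(dc)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(ncol(dc)))
  dimnames(dc) <- list(fnames, fnames)
  if (ncol(dc) == 1) {
    return(structure(list(dcor = dc, clusters = list(),
                          independents = fnames, threshold = threshold),
                     class = "wn_clusters"))
  }
  hc <- stats::hclust(stats::as.dist(1 - dc), method = "complete")
  # cut strictly below 1 - threshold: pairs at exactly the threshold stay apart
  membership <- stats::cutree(hc, h = (1 - threshold) * (1 - 1e-9))
  groups <- split(fnames, membership)
  sizes <- lengths(groups)
  structure(
    list(dcor = dc,
         clusters = unname(groups[sizes >= 2]),
         independents = unlist(unname(groups[sizes == 1])) %||% character(0),
         threshold = threshold,
         hclust = hc),
    class = "wn_clusters"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wn_clusters <- function(x, ...) {
  cat(sprintf("<wn_clusters> %d cluster(s) of >= 2 features + %d independent feature(s) at dCor > %g\n",
              length(x$clusters), length(x$independents), x$threshold))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d: %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Pick cluster representatives and form the reduced feature set
#'
#' For each cluster of two or more features, keeps the member with the
#' highest concatenated-nights AUC (ties broken lexicographically by feature
#' name, deterministically); independent features are carried forward
#' unchanged. The reduced set preserves a stable order: representatives in
#' cluster order, then independents.
#'
#' @param clusters A `wn_clusters` from [cluster_features()].
#' @param records A `wn_selection` with `auc_concat` for every clustered
#'   feature.
#' @return Character vector of forwarded feature names.
#' @export
pick_representatives <- function(clusters, records) {
  stopifnot(inherits(clusters, "wn_clusters"))
  reps <- vapply(clusters$clusters, function(cl) {
    auc <- records$auc_concat[match(cl, records$feature)]
    if (anyNA(auc)) {
      abort(paste0("missing concatenated AUC for: ",
                   paste(cl[is.na(auc)], collapse = ", ")))
    }
    best <- cl[auc == max(auc)]
    sort(best)[1]
  }, character(1))
  c(reps, clusters$independents)
}
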