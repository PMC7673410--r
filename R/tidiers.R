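#' Tidy a fitted whole-night classifier
#'
#' @param x A `wn_classifier`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`
#'   (standardised-scale log-odds), `estimate_raw` (per original feature
#'   unit).
#' @method tidy wn_classifier
#' @export
tidy.wn_classifier <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = unname(x$intercept),
           estimate_raw = unname(x$intercept -
             sum(x$coefficients * x$standardization$mean / x$standardization$sd))),
    tibble(term = x$feature_names,
           estimate = as.numeric(x$coefficients),
           estimate_raw = as.numeric(x$coefficients / x$standardization$sd))
  )
}

#' @rdname tidy.wn_classifier
#' @method glance wn_classifier
#' @export
glance.wn_classifier <- function(x, ...) {
  tibble(n_features = length(x$feature_names), n_train = x$n_train,
         lambda = x$lambda, converged = x$converged)
}

#' Tidy a pipeline run
#'
#' @param x A `wn_run`.
#' @param ... Unused.
#' @return The evaluation report tibble (one row per data slice x threshold).
#' @method tidy wn_run
#' @export
tidy.wn_run <- function(x, ...) x$report

#' @rdname tidy.wn_run
#' @method glance wn_run
#' @export
glance.wn_run <- function(x, ...) {
  m <- x$manifest
  tibble(n_subjects = m$n_subjects, n_train = m$n_train, n_test = m$n_test,
         n_features_in = m$n_features_in, n_concordant = m$n_concordant,
         n_age_corrected = m$n_age_corrected, n_selected = m$n_selected,
         n_clusters = m$n_clusters, n_independent = m$n_independent,
         n_reduced = m$n_reduced, n_final = m$n_final,
         univariate_fallback = m$univariate_fallback)
}

#' Plot a univariate selection record
#'
#' Per-night AUCs with their 95% CIs for the screened features, highlighting
#' the selected ones (CI lower bound above 0.5 on both nights).
#'
#' @param object A `wn_selection` from [select_features()].
#' @param top Show at most this many features, ordered by concatenated AUC.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wn_selection
#' @export
autoplot.wn_selection <- function(object, top = 40, ...) {
  d <- object %>%
    arrange(dplyr::desc(.data$auc_concat)) %>%
    head(top) %>%
    tidyr::pivot_longer(
      cols = c("auc_night1", "ci_lb_night1", "ci_ub_night1",
               "auc_night2", "ci_lb_night2", "ci_ub_night2"),
      names_to = c(".value", "night"), names_pattern = "(.*)_night(\\d)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$auc,
                                  y = stats::reorder(.data$feature, .data$auc_concat),
                                  colour = .data$selected)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lb, xmax = .data$ci_ub),
                             position = ggplot2::position_dodge2(width = 0.5),
                             size = 0.25) +
    ggplot2::facet_wrap(~night, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL, colour = "selected") +
    ggplot2::theme_minimal()
}

#' Plot a distance-correlation clustering
#'
#' Heatmap of the pairwise distance-correlation matrix, ordered by the
#' dendrogram, with the redundancy threshold as the midpoint of the scale.
#'
#' @param object A `wn_clusters` from [cluster_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wn_clusters
#' @export
autoplot.wn_clusters <- function(object, ...) {
  ord <- if (!is.null(object$hclust)) object$hclust$order else seq_len(ncol(object$dcor))
  dc <- object$dcor[ord, ord]
  d <- as_tibble(as.table(dc), .name_repair = ~c("f1", "f2", "dcor"))
  d$f1 <- factor(d$f1, levels = rownames(dc))
  d$f2 <- factor(d$f2, levels = rownames(dc))
  ggplot2::ggplot(d, ggplot2::aes(.data$f1, .data$f2, fill = .data$dcor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", mid = "steelblue1",
                                  high = "firebrick",
                                  midpoint = object$threshold, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "dCor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot pipeline evaluation metrics
#'
#' Sensitivity, specificity and adjusted PPV per data slice and threshold.
#'
#' @param object A `wn_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wn_run
#' @export
autoplot.wn_run <- function(object, ...) {
  d <- object$report %>%
    tidyr::pivot_longer(c("sensitivity", "specificity", "adjusted_ppv"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slice, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~target_sens,
                        labeller = ggplot2::labeller(
                          target_sens = function(v) paste("target train sens", v))) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
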