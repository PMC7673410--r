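#' Feature-count audit
#'
#' Checks the enumeration identities of the whole-night feature set: `C x B`
#' LP + `C x B` LCV + `C(C-1)/2 x B` synchrony features for `C` channels and
#' `B` bands (780 = 120 + 120 + 540 for the standard 10 x 12 configuration).
#'
#' @param n_channels Number of channels.
#' @param n_bands Number of bands.
#' @param observed Optional observed total to audit against (e.g. from a
#'   manifest); a mismatch is a hard failure.
#' @return Tibble with `n_lp`, `n_lcv`, `n_w`, `n_total`.
#' @export
feature_count_audit <- function(n_channels = 10, n_bands = 12, observed = NULL) {
  n_lp <- n_channels * n_bands
  n_w <- n_channels * (n_channels - 1) / 2 * n_bands
  out <- tibble(n_channels = n_channels, n_bands = n_bands,
                n_lp = n_lp, n_lcv = n_lp, n_w = n_w,
                n_total = 2 * n_lp + n_w)
  if (!is.null(observed) && observed != out$n_total) {
    abort(sprintf("feature count mismatch: observed %d, expected %d",
                  observed, out$n_total))
  }
  out
}

# deterministic per-stage seeds derived from one top-level seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483587L
}

#' Run the full screening pipeline
#'
#' Orchestrates the eight-step workflow end to end on a synthetic cohort (or
#' a supplied feature table): (1) generate/ingest features, (2) log-transform
#' synchrony and filter by two-night concordance on the training set, (3)
#' screen and remove age effects estimated on control training subjects, (4)
#' per-night AUC screening with DeLong CIs, (5) distance-correlation
#' clustering of the concatenated training vectors, (6) cluster
#' representatives + independents, (7) recursive feature elimination via
#' six-fold CV logistic regression, (8) final fit, threshold search at the
#' target training sensitivities, and per-night test evaluation with
#' sensitivity, specificity and prevalence-adjusted PPV.
#'
#' Every stage is computed from training rows only (test rows are carried
#' passively until evaluation), and all randomness derives deterministically
#' from `seed`, so re-running with the same config and seed reproduces the
#' report exactly, and deleting test rows leaves every training artifact
#' identical.
#'
#' If no feature survives the univariate screen (e.g. a null cohort), the
#' pipeline falls back to the single feature with the highest concatenated
#' training AUC so that a model and report are still produced; the manifest
#' flags this.
#'
#' @param config A [cohort_config()]; ignored when `table` is supplied.
#' @param seed Top-level seed, expanded into per-stage seeds.
#' @param table Optional precomputed feature table (skips generation).
#' @param signal If `TRUE`, generate raw signals and run the preprocessing /
#'   feature-extraction stages; otherwise use the fast feature-table tier.
#' @param prevalence Population prevalence for adjusted PPV (default 0.15).
#' @param sens_targets Target training sensitivities for threshold search
#'   (default `c(0.80, 0.90)`).
#' @param ccc_threshold,dcor_threshold,ci_level Stage parameters.
#' @return A `wn_run` object: `report` (tibble in the layout of the
#'   evaluation tables: one row per data slice x threshold), `model`,
#'   `selection`, `clusters`, `conditioning`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, table = NULL,
                         signal = FALSE, prevalence = 0.15,
                         sens_targets = c(0.80, 0.90),
                         ccc_threshold = 0.7, dcor_threshold = 0.7,
                         ci_level = 0.95) {
  stages <- list()
  if (is.null(table)) {
    config$seed <- .stage_seed(seed, 1L)
    if (signal) {
      sim <- simulate_cohort(config)
      grids <- lapply(sim$recordings, preprocess_recording)
      table <- assemble_features(grids, sim$meta, channels = config$channels)
      stages$rejection <- dplyr::bind_rows(lapply(grids, rejection_summary))
    } else {
      table <- simulate_feature_table(config)
    }
  }
  n_features_in <- length(.feature_cols(table))

  # step 2: scale + concordance filter (train-derived)
  table <- log_transform_synchrony(table)
  conc <- concordance_filter(table, threshold = ccc_threshold)
  table <- apply_concordance_filter(table, conc)

  # step 3: age screening and correction (control-train derived)
  table <- age_screen_and_correct(table)
  agerep <- age_report(table)

  # step 4: per-night univariate AUC screen (train only)
  records <- select_features(table, level = ci_level)
  selected <- records$feature[records$selected]
  fallback <- length(selected) == 0
  if (fallback) {
    selected <- records$feature[which.max(records$auc_concat)]
  }
  sel_records <- records[records$feature %in% selected, ]
  oriented <- orient_features(table, sel_records)

  # steps 5-6: cluster concatenated training vectors, pick representatives
  tr <- dplyr::filter(oriented, .data$split == "train")
  clusters <- cluster_features(as.matrix(tr[, selected, drop = FALSE]),
                               threshold = dcor_threshold)
  reduced <- pick_representatives(clusters, sel_records)

  # step 7: RFE via six-fold CV
  rfe <- rfe_cv(oriented, reduced, folds = 6, seed = .stage_seed(seed, 7L))

  # step 8: final model, thresholds, evaluation
  model <- fit_logistic(oriented, rfe$features)
  thr <- lapply(sens_targets, function(ts) {
    threshold_for_sensitivity(model, oriented, ts)
  })
  model$thresholds <- stats::setNames(
    vapply(thr, `[[`, numeric(1), "cutoff"),
    sprintf("sens>=%.2f", sens_targets))

  slices <- list(
    `training (both nights)` = dplyr::filter(oriented, .data$split == "train"),
    `test night 1` = dplyr::filter(oriented, .data$split == "test", .data$night == 1),
    `test night 2` = dplyr::filter(oriented, .data$split == "test", .data$night == 2)
  )
  report <- purrr::map_dfr(seq_along(thr), function(i) {
    purrr::map_dfr(names(slices), function(nm) {
      sl <- slices[[nm]]
      if (nrow(sl) == 0) return(NULL)
      dplyr::bind_cols(
        tibble(slice = nm, target_sens = sens_targets[i],
               achieved_train_sens = thr[[i]]$achieved_sens),
        evaluate_classifier(model, sl, thr[[i]]$cutoff, prevalence))
    })
  })

  manifest <- list(
    seed = seed,
    n_subjects = length(unique(table$subject_id)),
    n_train = length(unique(table$subject_id[table$split == "train"])),
    n_test = length(unique(table$subject_id[table$split == "test"])),
    n_features_in = n_features_in,
    n_concordant = sum(conc$retained),
    n_age_corrected = sum(agerep$corrected),
    n_selected = if (fallback) 0L else length(selected),
    univariate_fallback = fallback,
    n_clusters = length(clusters$clusters),
    n_independent = length(clusters$independents),
    n_reduced = length(reduced),
    n_final = length(rfe$features),
    final_features = rfe$features,
    prevalence = prevalence
  )
  structure(
    list(report = report, model = model, selection = records,
         clusters = clusters, concordance = conc, age = agerep,
         rfe = rfe, manifest = manifest, table = oriented,
         stages = stages),
    class = "wn_run"
  )
}

#' @export
print.wn_run <- function(x, ...) {
  m <- x$manifest
  cat("<wn_run> whole-night EEG screening pipeline\n")
  cat(sprintf("  features: %d -> %d concordant -> %d selected -> %d reduced -> %d final\n",
              m$n_features_in, m$n_concordant,
              if (m$univariate_fallback) 0 else m$n_selected,
              m$n_reduced, m$n_final))
  if (m$univariate_fallback) {
    cat("  (no feature passed the univariate screen; fell back to top concatenated AUC)\n")
  }
  cat(sprintf("  final model: %s\n", paste(m$final_features, collapse = ", ")))
  print(as.data.frame(dplyr::mutate(dplyr::select(
    x$report, "slice", "target_sens", "cutoff", "sensitivity",
    "specificity", "auc", "adjusted_ppv"),
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))), row.names = FALSE)
  invisible(x)
}

#' Write a feature table as TSV
#'
#' Metadata columns first, then feature columns; a JSON sidecar records the
#' band set and provenance fields.
#'
#' @param tbl A feature table.
#' @param path Output TSV path.
#' @param provenance Optional named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path, provenance = list()) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- c(list(bands = eeg_bands(),
                    n_features = length(.feature_cols(tbl))), provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return A feature table tibble.
#' @export
read_feature_table <- function(path) {
  out <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
  out$group <- factor(out$group, levels = c("control", "PTSD"))
  out
}
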