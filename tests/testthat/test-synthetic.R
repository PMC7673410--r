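test_that("config validation enforces the documented invariants", {
  expect_error(cohort_config(duration = 123), "multiple of the 5-s")
  expect_error(cohort_config(duration = 0), "multiple of the 5-s")
  expect_error(cohort_config(night_consistency = 0), "night_consistency")
  expect_error(cohort_config(night_consistency = 1.2), "night_consistency")
  expect_error(cohort_config(n_ptsd = 0), "positive")
  expect_error(cohort_config(artifact_rate = 1.5), "artifact_rate")
  expect_error(cohort_config(planted = c("LP-C9-Xx" = 1)), NA) # checked later
  expect_error(simulate_feature_table(cohort_config(planted = c("LP-C9-Xx" = 1))),
               "not in the feature set")
})

test_that("the default roster mirrors the study design", {
  cfg <- cohort_config(seed = 1)
  set.seed(1)
  meta <- wholenight:::.simulate_meta(cfg)
  expect_equal(nrow(meta), 78)
  expect_equal(sum(meta$group == "PTSD"), 31)
  expect_equal(sum(meta$split == "train"), 47)
  # consecutive-enrolment split: 18 of the first 47 are PTSD, 13 of the rest
  expect_equal(sum(meta$group == "PTSD" & meta$split == "train"), 18)
  expect_equal(sum(meta$group == "PTSD" & meta$split == "test"), 13)
  expect_false(anyDuplicated(meta$subject_id) > 0)
  expect_true(all(meta$age >= 24 & meta$age <= 51))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- cohort_config(n_ptsd = 1, n_control = 1, duration = 30, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$recordings[[1]]$samples, s2$recordings[[1]]$samples)
  expect_identical(s1$meta, s2$meta)
  t1 <- simulate_feature_table(table_config())
  t2 <- simulate_feature_table(table_config())
  expect_identical(t1, t2)
  # a different seed changes the data
  t3 <- simulate_feature_table(cohort_config(seed = 43))
  expect_false(identical(t1, t3))
})

test_that("feature-table tier: perfect night consistency means identical nights", {
  cfg <- cohort_config(n_ptsd = 5, n_control = 5, night_consistency = 1,
                       seed = 2)
  tbl <- simulate_feature_table(cfg)
  rep <- concordance_filter(tbl)
  expect_true(all(rep$ccc == 1))
})

test_that("feature-table tier: between-night correlation tracks the target", {
  cfg <- table_config(night_consistency = 0.8, effect_delta_power = 0,
                      effect_alpha_sync = 0, effect_gamma_sync = 0)
  tbl <- simulate_feature_table(cfg)
  rep <- concordance_filter(tbl)
  # mean CCC across 780 features concentrates near the configured rho
  expect_lt(abs(mean(rep$ccc) - 0.8), 0.05)
})

test_that("feature-table tier: group effects land on the configured bands", {
  cfg <- table_config(effect_delta_power = -1.5, effect_alpha_sync = 1.5,
                      effect_gamma_sync = 1.5)
  tbl <- simulate_feature_table(cfg)
  info <- parse_feature_names(wholenight:::.feature_cols(tbl))
  tstat <- function(f) {
    unname(t.test(tbl[[f]][tbl$group == "PTSD"],
                  tbl[[f]][tbl$group == "control"])$statistic)
  }
  lp_delta <- info$name[info$type == "LP" & info$band %in% c("Ld", "Hd")]
  expect_true(all(vapply(lp_delta, tstat, numeric(1)) < 0))
  # alpha effect topography: left-hemisphere pairs and pairs involving C4
  w_alpha <- c("W-C3-F3-Ha", "W-C3-P3-Ha", "W-F3-O1-Ha", "W-C4-P3-Ha",
               "W-C4-T4-Ha", "W-C4-F3-Ha")
  expect_true(all(vapply(w_alpha, tstat, numeric(1)) > 0))
  # right-hemisphere non-C4 alpha pairs carry no effect
  w_alpha_null <- vapply(c("W-F4-O2-Ha", "W-P4-T4-Ha"), tstat, numeric(1))
  expect_lt(max(abs(w_alpha_null)), 3.5)
  # gamma effect on cross-hemisphere fronto-central pairs only
  expect_gt(tstat("W-C4-F3-Lg"), 0)
  expect_gt(tstat("W-C3-F4-Lg"), 0)
  # unaffected bands show no systematic shift
  lp_beta <- info$name[info$type == "LP" & info$band == "Lb"]
  ts <- vapply(lp_beta, tstat, numeric(1))
  expect_lt(abs(mean(ts)), 1)
})

test_that("feature-table tier: planted effects override band effects", {
  planted <- c("LCV-T3-Hs" = 2.5)
  cfg <- table_config(effect_delta_power = 0, effect_alpha_sync = 0,
                      effect_gamma_sync = 0, planted = planted)
  tbl <- simulate_feature_table(cfg)
  d_obs <- (mean(tbl$`LCV-T3-Hs`[tbl$group == "PTSD"]) -
            mean(tbl$`LCV-T3-Hs`[tbl$group == "control"])) / 0.03
  expect_gt(d_obs, 1.5) # standardised shift near the planted 2.5
})

test_that("null cohorts give per-night DeLong CIs containing 0.5 for ~95% of features", {
  cfg <- table_config(effect_delta_power = 0, effect_alpha_sync = 0,
                      effect_gamma_sync = 0)
  tbl <- log_transform_synchrony(simulate_feature_table(cfg))
  rec <- suppressWarnings(select_features(tbl))
  # orientation makes night-1 AUC >= 0.5, so test the unoriented CI via
  # symmetry: CI contains 0.5 iff oriented lower bound <= 0.5
  covered <- rec$ci_lb_night1 <= 0.5
  expect_gt(mean(covered), 0.92)
})

test_that("signal tier: delta power is reduced in PTSD recordings", {
  cfg <- cohort_config(n_ptsd = 4, n_control = 4, n_nights = 1, duration = 60,
                       artifact_rate = 0, effect_delta_power = -3, seed = 6)
  sim <- simulate_cohort(cfg)
  grids <- lapply(sim$recordings, segment_epochs)
  tab <- assemble_features(grids, sim$meta)
  for (f in c("LP-C3-Ld", "LP-C3-Hd", "LP-O2-Ld")) {
    tt <- t.test(tab[[f]][tab$group == "PTSD"], tab[[f]][tab$group == "control"])
    expect_lt(unname(tt$statistic), 0)
  }
  # non-delta band unaffected in sign systematically
  expect_gt(mean(tab$`LP-C3-Ha`[tab$group == "PTSD"]) -
            mean(tab$`LP-C3-Ha`[tab$group == "control"]), -1)
})

test_that("signal tier: WPLI rises monotonically with coupling strength", {
  strengths <- c(0, 0.5, 1, 1.5, 2)
  mean_w <- vapply(strengths, function(cb) {
    mean(vapply(1:6, function(s) {
      cfg <- cohort_config(n_ptsd = 1, n_control = 1, n_nights = 1,
                           duration = 60, artifact_rate = 0,
                           channels = c("C3", "C4", "F3", "P3"),
                           coupling_base = cb, seed = 100 + s)
      sim <- simulate_cohort(cfg)
      g <- segment_epochs(sim$recordings[[1]])
      wpli(g, "C4", "P3", "Ha")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_w) > 0))
  expect_lt(mean_w[1], 0.25)
  expect_gt(mean_w[5], 0.75)
})

test_that("signal tier: with artifact_rate = 0 fewer than 1% of epochs are rejected", {
  cfg <- cohort_config(n_ptsd = 2, n_control = 2, n_nights = 1, duration = 120,
                       artifact_rate = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  grids <- lapply(sim$recordings, preprocess_recording)
  rej <- dplyr::bind_rows(lapply(grids, rejection_summary))
  expect_lt(sum(rej$n_epochs - rej$n_kept) / sum(rej$n_epochs), 0.01)
})

test_that("signal tier: injected artifacts are caught by the intended rules", {
  cfg <- cohort_config(n_ptsd = 1, n_control = 1, n_nights = 1, duration = 300,
                       artifact_rate = 0.1, seed = 9)
  sim <- simulate_cohort(cfg)
  grids <- lapply(sim$recordings, preprocess_recording)
  rej <- dplyr::bind_rows(lapply(grids, rejection_summary))
  frac <- sum(rej$n_epochs - rej$n_kept) / sum(rej$n_epochs)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.2)
  expect_gt(sum(rej$n_emg), 0)
  expect_gt(sum(rej$n_movement), 0)
})
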