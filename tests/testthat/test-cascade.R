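test_that("survival significance filter keeps hazard-linked outliers", {
  cfg <- sim_config(seed = 51, n_et = 300, n_rna_features = 40,
                    n_rppa_features = 10, effect_shift = 2.5,
                    hazard_ratio_pd = 3)
  pair <- simulate_cohort_pair(cfg)
  tt <- truth_table(cfg)
  planted <- tt$feature_id[tt$informative & tt$platform == "RNA"]
  nulls <- setdiff(tt$feature_id[tt$platform == "RNA"], planted)
  keep <- survival_significance_filter(c(planted, nulls), pair$et,
                                       cascade_config())
  expect_gt(mean(planted %in% keep), mean(nulls %in% keep))
  detail <- attr(keep, "detail")
  expect_true(all(detail$kept == (detail$pfs_p < 0.05 & detail$os_p < 0.05),
                  na.rm = TRUE))
  expect_equal(length(survival_significance_filter(character(), pair$et,
                                                   cascade_config())), 0)
})

test_that("fold-change filter is a group-mean difference on the z scale", {
  pair <- simulate_cohort_pair(small_config(52, effect_shift = 1.5))
  tr <- pair$tr
  feats <- colnames(expr_matrix(tr, "RNA"))
  keep0 <- fold_change_filter(feats, tr, cascade_config(fold_change_abs = 1e-9))
  expect_equal(length(keep0), length(feats))  # vacuous threshold
  # a feature with identical group means is dropped
  mat <- expr_matrix(tr, "RNA")
  mat[, 2] <- 0.7   # constant -> all group means equal
  tr2 <- cohort(tr$clinical, mat)
  keep <- fold_change_filter(feats, tr2, cascade_config())
  expect_false(colnames(mat)[2] %in% keep)
  detail <- attr(keep, "detail")
  expect_equal(detail$diff_ai[2], 0)
})

test_that("consistency filter applies the criterion conjunctions", {
  rules <- tibble::tibble(
    feature_id = c("keep_auc", "keep_surv", "drop_tr", "drop_et"),
    response_iauc = c(0.90, 0.55, 0.55, 0.95),
    tr_pfs_p = c(0.50, 0.01, 0.50, 0.90),
    tr_os_p = c(0.50, 0.05, 0.50, 0.90),
    et_pfs_p = c(0.01, 0.01, 0.01, 0.90),
    et_os_p = c(0.05, 0.50, 0.50, 0.90))
  kept <- cohort_consistency_filter(rules, cascade_config())
  # keep_auc: TR criterion by AUC, ET criterion by ET PFS strict + ET OS relaxed
  expect_true("keep_auc" %in% kept)
  expect_true("keep_surv" %in% kept)
  expect_false("drop_tr" %in% kept)   # no TR-arm criterion satisfied
  expect_false("drop_et" %in% kept)   # no ET-arm criterion satisfied
  expect_error(cohort_consistency_filter(rules,
                                         cascade_config(tr_criteria = character())),
               "no active criteria")
})

test_that("greedy panel selection finds a dominant feature and stops", {
  pair <- simulate_cohort_pair(small_config(53))
  tr <- pair$tr
  mat <- expr_matrix(tr, "RNA")
  pd <- tr$clinical$response[match(rownames(mat),
                                   tr$clinical$sample_id)] == "PD"
  mat[, 1] <- as.numeric(pd) + rnorm(44, 0, 1e-3)  # perfect separator
  tr2 <- cohort(tr$clinical, mat)
  rules <- fit_cutoff_rules(tr2, colnames(mat)[1:8])
  sel <- cumulative_panel_selection(rules, tr2,
                                    cascade_config(panel_mode = "improve"))
  expect_equal(attr(sel, "panel"), colnames(mat)[1])
  expect_equal(sel$response_auc, 1)
  # a single candidate is returned trivially
  one <- cumulative_panel_selection(rules[3, ], tr2, cascade_config())
  expect_equal(attr(one, "panel"), rules$feature_id[3])
  expect_error(cumulative_panel_selection(rules[0, ], tr2, cascade_config()),
               "empty candidate")
})

test_that("fixed-size selection fills the configured panel", {
  pair <- simulate_cohort_pair(small_config(54))
  rules <- fit_cutoff_rules(pair$tr, colnames(expr_matrix(pair$tr, "RNA"))[1:12])
  sel <- cumulative_panel_selection(rules, pair$tr,
                                    cascade_config(panel_mode = "fixed",
                                                   rna_panel_size = 6))
  expect_equal(length(attr(sel, "panel")), 6)
  expect_equal(sel$step, 1:6)
})

test_that("every cascade stage only removes features", {
  for (seed in c(61, 62, 63)) {
    pair <- simulate_cohort_pair(small_config(seed, n_et = 120))
    rep <- run_cascade(pair$tr, pair$et, cascade_config())
    st <- rep$stages
    for (pl in unique(st$platform)) {
      feats <- st$features[st$platform == pl]
      for (i in seq_along(feats)[-1]) {
        expect_true(all(feats[[i]] %in% feats[[i - 1]]) ||
                      st$stage[st$platform == pl][i] == "panel")
      }
      expect_true(all(st$n_output[st$platform == pl] <=
                        st$n_input[st$platform == pl]))
    }
  }
})

test_that("a screen with no outliers yields an empty, error-free report", {
  pair <- simulate_cohort_pair(small_config(55))
  squash <- function(co) {
    rna <- expr_matrix(co, "RNA"); rna[] <- pmin(pmax(rna, -1.9), 1.9)
    rppa <- expr_matrix(co, "RPPA"); rppa[] <- pmin(pmax(rppa, -1.9), 1.9)
    cohort(co$clinical, rna, rppa)
  }
  rep <- run_cascade(squash(pair$tr), squash(pair$et), cascade_config())
  expect_equal(rep$rna_panel, character())
  expect_equal(rep$rppa_panel, character())
  expect_true(all(rep$stages$n_output == 0))
})

test_that("the cascade is deterministic and monotone in its thresholds", {
  pair <- simulate_cohort_pair(small_config(56, n_et = 120))
  a <- run_cascade(pair$tr, pair$et, cascade_config())
  b <- run_cascade(pair$tr, pair$et, cascade_config())
  expect_equal(a$stages, b$stages)
  expect_equal(a$rna_panel, b$rna_panel)
  # relaxing thresholds can only widen each filtering stage
  tight <- cascade_config()
  loose <- cascade_config(survival_alpha = 0.5, fold_change_abs = 0.05,
                          response_auc_min = 0.5, strict_alpha = 0.5,
                          relaxed_alpha = 0.6)
  sa <- run_cascade(pair$tr, pair$et, tight)$stages
  sb <- run_cascade(pair$tr, pair$et, loose)$stages
  for (i in seq_len(nrow(sa))) {
    if (sa$stage[i] != "panel") {
      expect_true(all(sa$features[[i]] %in% sb$features[[i]]))
    }
  }
})
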