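mk_rules <- function(feature_ids, platform, cutoff, direction = "ge") {
  tibble::tibble(feature_id = feature_ids, platform = platform,
                 cutoff = cutoff, direction = direction)
}

test_that("cumulative scores count satisfied rules per platform", {
  pair <- simulate_cohort_pair(small_config(71))
  tr <- pair$tr
  # cutoffs below every value -> every ge-rule fires
  always <- mk_rules(colnames(tr$rna)[1:6], "RNA", -99)
  s <- cumulative_score(tr, always)
  expect_true(all(s$rna_score == 6))
  # rules from both platforms add into the combined score
  both <- dplyr::bind_rows(always, mk_rules(colnames(tr$rppa)[1:3], "RPPA", -99))
  s2 <- cumulative_score(tr, both)
  with_rppa <- s2$sample_id %in% rownames(tr$rppa)
  expect_true(all(s2$combined_score[with_rppa] == 9))
  expect_true(all(is.na(s2$combined_score[!with_rppa])))
  expect_true(all(is.na(s2$rppa_score[!with_rppa])))
  expect_error(cumulative_score(tr, always[0, ]), "empty panel")
})

test_that("adding a rule never decreases any sample's score", {
  pair <- simulate_cohort_pair(small_config(72))
  tr <- pair$tr
  rules <- fit_cutoff_rules(tr, colnames(tr$rna)[1:8])
  for (k in 2:8) {
    s_small <- cumulative_score(tr, rules[1:(k - 1), ])$rna_score
    s_big <- cumulative_score(tr, rules[1:k, ])$rna_score
    expect_true(all(s_big >= s_small))
  }
})

test_that("score ROC matches trapezoidal integration and handles ties", {
  set.seed(73)
  for (i in 1:20) {
    scores <- sample(0:10, 60, replace = TRUE)
    labels <- runif(60) < 0.4
    if (length(unique(labels)) < 2) next
    r <- score_roc(scores, labels)
    expect_equal(r$auc, trapezoid_auc(scores, labels), tolerance = 1e-10)
  }
  sep <- score_roc(c(1, 2, 3, 8, 9, 10), c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(sep$auc, 1)
  tied <- score_roc(rep(4, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$p_value, 1)
  # AUC is rank-based, hence invariant under increasing transforms
  s <- sample(0:15, 50, replace = TRUE); l <- runif(50) < 0.5
  expect_equal(score_roc(s, l)$auc, score_roc(s^3 + 2, l)$auc)
})

test_that("PD-anchored dichotomization uses the ceiling convention", {
  scores <- setNames(c(5, 5, 6, 7, 1, 2, 3, 8), paste0("s", 1:8))
  g <- dichotomize_by_pd(scores, pd_samples = paste0("s", 1:4),
                         anchor = "median")
  expect_equal(g$threshold, 6)  # median 5.5 -> ceiling 6
  expect_equal(sort(g$assignment$sample_id[g$assignment$risk == "high"]),
               c("s3", "s4", "s8"))
  same <- dichotomize_by_pd(setNames(rep(3, 5), paste0("s", 1:5)),
                            pd_samples = paste0("s", 1:5), anchor = "mean")
  expect_equal(same$threshold, 3)
  # a pre-derived threshold is reused unchanged (validation-arm contract)
  reuse <- dichotomize_by_pd(scores, threshold = g$threshold)
  expect_equal(reuse$threshold, 6)
  expect_equal(reuse$assignment, g$assignment)
  expect_error(dichotomize_by_pd(scores, pd_samples = "nope"), "empty PD")
})

test_that("risk-group stratification reduces to the component tests", {
  pair <- simulate_cohort_pair(small_config(74))
  tr <- pair$tr
  scores <- setNames(as.numeric(tr$clinical$response == "PD"),
                     tr$clinical$sample_id)
  g <- dichotomize_by_pd(scores, names(scores)[scores == 1], "mean")
  st <- stratified_survival(g, tr, "PFS")
  direct <- log_rank_test(tr$clinical$pfs_time, tr$clinical$pfs_event,
                          tr$clinical$response)
  expect_equal(st$logrank$chi_square, direct$chi_square, tolerance = 1e-10)
  expect_equal(sort(unique(st$km$risk)), c("high", "low"))
  # identical survival in both groups -> p = 1
  cl <- tr$clinical
  cl$pfs_time <- rep(c(100, 200), 22); cl$pfs_event <- TRUE
  tr2 <- cohort(cl, tr$rna, tr$rppa)
  g2 <- dichotomize_by_pd(setNames(rep(c(0, 1), each = 22), cl$sample_id),
                          cl$sample_id, "mean")
  expect_equal(stratified_survival(g2, tr2, "PFS")$logrank$p_value, 1)
})

test_that("risk scores separate planted responders from progressors", {
  ok <- sapply(1:20, function(seed) {
    cfg <- small_config(seed, effect_shift = 1.5)
    pair <- simulate_cohort_pair(cfg)
    tt <- truth_table(cfg)
    planted <- tt$feature_id[tt$informative & tt$platform == "RNA"]
    rules <- fit_cutoff_rules(pair$tr, planted)
    s <- cumulative_score(pair$tr, rules)
    pd <- pair$tr$clinical$response == "PD"
    median(s$rna_score[pd]) > median(s$rna_score[!pd])
  })
  expect_gte(mean(ok), 0.95)
})

test_that("scatter table keeps only dual-platform samples", {
  pair <- simulate_cohort_pair(small_config(75))
  tr <- pair$tr
  rules <- dplyr::bind_rows(mk_rules(colnames(tr$rna)[1:4], "RNA", 0),
                            mk_rules(colnames(tr$rppa)[1:2], "RPPA", 0))
  s <- cumulative_score(tr, rules)
  sc <- scatter_table(s, tr)
  expect_equal(nrow(sc), nrow(tr$rppa))
  expect_equal(attr(sc, "n_excluded"), nrow(tr$clinical) - nrow(tr$rppa))
  expect_true(all(sc$label %in% c("CR", "PD")))
  rna_only <- cumulative_score(tr, rules[rules$platform == "RNA", ])
  expect_warning(scatter_table(rna_only, tr), "both platform")
})
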