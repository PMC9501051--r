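replica_clinical <- function() {
  # a cohort constructed to match the printed baseline counts of the
  # 44-sample study arm: 34 CR / 10 PD with the tabulated characteristic
  # splits (counts, not individual patients, drive every categorical test)
  fill <- function(n, n_yes, yes, no) c(rep(yes, n_yes), rep(no, n - n_yes))
  tibble::tibble(
    sample_id = sprintf("R%02d", 1:44),
    cohort_arm = "TR",
    response = fill(44, 34, "CR", "PD"),
    regimen = c(fill(34, 17, "AI", "SERM"),
                c(rep("AI", 5), "SERM", "SERM", "SERM", "SERD", "SERD")),
    age_years = 58,
    t_stage = c(fill(34, 4, "T3_4", "T1_2"), fill(10, 2, "T3_4", "T1_2")),
    n_stage = c(fill(34, 17, "N1_3", "N0"), fill(10, 7, "N1_3", "N0")),
    m_stage = c(fill(34, 0, "M1", "M0"), fill(10, 2, "M1", "M0")),
    stage = c(fill(34, 7, "III_IV", "I_II"), fill(10, 6, "III_IV", "I_II")),
    pfs_time = 1000,
    pfs_event = c(fill(34, 0, TRUE, FALSE), fill(10, 9, TRUE, FALSE)),
    os_time = 1000,
    os_event = c(fill(34, 2, TRUE, FALSE), fill(10, 6, TRUE, FALSE))
  )
}

test_that("baseline table reproduces the printed contingency p-values", {
  cl <- replica_clinical()
  rna <- matrix(rnorm(44 * 3), 44, 3,
                dimnames = list(cl$sample_id, paste0("G", 1:3)))
  tab <- baseline_table(cohort(cl, rna))
  p_of <- function(ch) tab$p_value[tab$characteristic == ch]
  expect_equal(round(p_of("m_stage"), 3), 0.048)
  expect_equal(round(p_of("stage"), 3), 0.043)
  expect_equal(round(p_of("t_stage"), 3), 0.606)
  expect_equal(round(p_of("n_stage"), 3), 0.306)
  expect_equal(round(p_of("regimen_SERD"), 3), 0.048)
  expect_equal(round(p_of("regimen_SERM"), 3), 0.306)
  expect_equal(round(p_of("regimen_AI"), 3), 1)
  expect_equal(tab$p_display[tab$characteristic == "pfs_event"], "<0.001")
  expect_equal(tab$p_display[tab$characteristic == "os_event"], "<0.001")
  # cell text carries count and percentage of the group total
  expect_equal(tab$PD[tab$characteristic == "m_stage"], "2 (20.0%)")
  expect_equal(tab$CR[tab$characteristic == "stage"], "7 (20.6%)")
  expect_true(all(tab$test[tab$characteristic != "age_years"] == "fisher"))
  expect_equal(tab$test[tab$characteristic == "age_years"], "wilcoxon")
})

test_that("three-group baseline comparisons dispatch to rxc tests", {
  cl <- replica_clinical()
  rna <- matrix(rnorm(44 * 2), 44, 2,
                dimnames = list(cl$sample_id, c("G1", "G2")))
  tab <- baseline_table(cohort(cl, rna), grouping = "pd_regimen")
  expect_true(all(c("AI_PD", "SERM_SERD_PD", "CR") %in% names(tab)))
  expect_equal(tab$test[tab$characteristic == "age_years"], "kruskal-wallis")
  expect_true(all(tab$test[tab$characteristic != "age_years"] == "fisher-rxc"))
})

test_that("expression summaries report medians, ranges and wilcoxon p", {
  pair <- simulate_cohort_pair(small_config(81))
  tr <- pair$tr
  mat <- expr_matrix(tr, "RNA")
  mat[, 3] <- 1.25  # constant feature
  tr2 <- cohort(tr$clinical, mat)
  tab <- expression_summary_table(tr2, colnames(mat)[1:4])
  expect_equal(nrow(tab), 4)
  expect_equal(tab$p_value[3], 1)
  expect_equal(tab$cr[3], tab$pd[3])
  f <- colnames(mat)[1]
  pd <- tr2$clinical$response == "PD"
  expect_equal(tab$p_value[1],
               wilcoxon_rank_sum(mat[!pd, f], mat[pd, f])$p_value)
})

test_that("the pipeline writes a complete, reproducible report bundle", {
  cfg <- small_config(82, n_et = 120)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, cascade_config(), outdir = d1)
  r2 <- run_pipeline(cfg, cascade_config(), outdir = d2)
  expect_true(all(c("cascade_stages.tsv", "baseline_tr.tsv", "summary.json")
                  %in% basename(r1$paths)))
  for (f in basename(r1$paths)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # every report file opens with the seed + config header
  tsvs <- grep("tsv$", r1$paths, value = TRUE)
  for (f in tsvs) expect_match(readLines(f, n = 1), "^# crossres seed=82")
})

test_that("tidiers and autoplot methods cover the result types", {
  pair <- simulate_cohort_pair(small_config(83, n_et = 120))
  flags <- flag_features(pair$tr, screen_groups(pair$tr))
  expect_true(all(c("group", "feature_id") %in% names(tidy(flags))))
  part <- venn_partition(flags)
  expect_equal(sum(glance(part)), sum(part$counts))
  rep <- run_cascade(pair$tr, pair$et, cascade_config())
  expect_true(is.data.frame(tidy(rep)))
  expect_equal(glance(rep)$panel_mode, "fixed")
  rules <- fit_cutoff_rules(pair$tr, colnames(pair$tr$rna)[1:5])
  s <- cumulative_score(pair$tr, rules)
  roc <- score_roc(s$rna_score,
                   pair$tr$clinical$response[match(s$sample_id,
                                                   pair$tr$clinical$sample_id)] == "PD")
  expect_equal(glance(roc)$auc, roc$auc)
  expect_s3_class(autoplot(roc), "ggplot")
  g <- dichotomize_by_pd(s, pair$tr$clinical$sample_id[
    pair$tr$clinical$response == "PD"], score_col = "rna_score")
  st <- stratified_survival(g, pair$tr, "OS")
  expect_s3_class(autoplot(st), "ggplot")
  expect_equal(glance(st)$endpoint, "OS")
  expect_s3_class(autoplot(rep), "ggplot")
  cm <- pearson_matrix(pair$tr, colnames(pair$tr$rna)[1:4])
  expect_equal(nrow(tidy(cm)), 6)
})
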