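format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 1e-3, "<0.001", sprintf("%.3f", p)))
}

med_range <- function(x) {
  if (length(x) == 0 || all(is.na(x))) return("-")
  sprintf("%.2f (%.2f-%.2f)", median(x, na.rm = TRUE),
          min(x, na.rm = TRUE), max(x, na.rm = TRUE))
}

#' Baseline characteristics table
#'
#' Per-characteristic counts, percentages and medians with ranges for the
#' TR cohort split by response (CR vs PD), with the appropriate test
#' p-value: Wilcoxon rank-sum for age, Fisher's exact test for the
#' dichotomous characteristics (each regimen tested as itself vs the
#' rest). With `grouping = "pd_regimen"` the comparison is CR vs AI-PD vs
#' SERM/SERD-PD using Kruskal-Wallis / Fisher on the full table.
#'
#' @param cohort TR-arm [cohort()].
#' @param grouping `"response"` (default) or `"pd_regimen"`.
#' @return Tibble: `characteristic`, `level`, `overall`, one column per
#'   group, `p_value`, `test`, `p_display` (3 decimals, `<0.001` floor).
#' @export
baseline_table <- function(cohort, grouping = c("response", "pd_regimen")) {
  grouping <- arg_match(grouping)
  cl <- cohort$clinical
  grp <- if (grouping == "response") cl$response else
    unname(screen_groups(cohort)[cl$sample_id])
  levels_g <- sort(unique(grp))

  count_cell <- function(flag, sel) {
    n <- sum(flag[sel]); tot <- sum(sel)
    sprintf("%d (%.1f%%)", n, if (tot > 0) 100 * n / tot else 0)
  }
  cat_row <- function(name, flag, level) {
    cells <- c(count_cell(flag, rep(TRUE, length(flag))),
               map_chr(levels_g, ~ count_cell(flag, grp == .x)))
    p <- if (grouping == "response") {
      tab <- vapply(levels_g, function(g) {
        c(sum(flag & grp == g), sum(!flag & grp == g))
      }, numeric(2))
      fisher_exact_2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])$p_value
    } else {
      tab <- table(flag, grp)
      if (nrow(tab) < 2) 1 else stats::fisher.test(tab)$p.value
    }
    tibble(characteristic = name, level = level,
           overall = cells[1], !!!set_names(as.list(cells[-1]), levels_g),
           p_value = p,
           test = if (grouping == "response") "fisher" else "fisher-rxc")
  }
  num_row <- function(name, x) {
    cells <- c(med_range(x), map_chr(levels_g, ~ med_range(x[grp == .x])))
    p <- if (length(levels_g) == 2) {
      wilcoxon_rank_sum(x[grp == levels_g[1]], x[grp == levels_g[2]])$p_value
    } else {
      kruskal_wallis(split(x, grp))$p_value
    }
    tibble(characteristic = name, level = "median (range)",
           overall = cells[1], !!!set_names(as.list(cells[-1]), levels_g),
           p_value = p,
           test = if (length(levels_g) == 2) "wilcoxon" else "kruskal-wallis")
  }

  out <- bind_rows(
    num_row("age_years", cl$age_years),
    cat_row("t_stage", cl$t_stage == "T3_4", "T3_4"),
    cat_row("n_stage", cl$n_stage == "N1_3", "N1_3"),
    cat_row("m_stage", cl$m_stage == "M1", "M1"),
    cat_row("stage", cl$stage == "III_IV", "III_IV"),
    cat_row("pfs_event", cl$pfs_event, "progressed"),
    cat_row("os_event", cl$os_event, "died"),
    cat_row("regimen_AI", cl$regimen == "AI", "AI"),
    cat_row("regimen_SERM", cl$regimen == "SERM", "SERM"),
    cat_row("regimen_SERD", cl$regimen == "SERD", "SERD")
  )
  mutate(out, p_display = format_p(.data$p_value))
}

#' Expression summary of selected features by response group
#'
#' Median (range) per group with the Wilcoxon rank-sum p-value, the layout
#' of the per-panel expression tables the pipeline reports.
#'
#' @param cohort TR-arm [cohort()].
#' @param features Feature ids.
#' @param platform `"RNA"` or `"RPPA"`.
#' @return Tibble with one row per feature.
#' @export
expression_summary_table <- function(cohort, features,
                                     platform = c("RNA", "RPPA")) {
  platform <- arg_match(platform)
  mat <- expr_matrix(cohort, platform)
  cl <- cohort$clinical[match(rownames(mat), cohort$clinical$sample_id), ]
  map(features, function(f) {
    x <- mat[, f]
    cr <- x[cl$response == "CR"]; pd <- x[cl$response == "PD"]
    p <- if (length(unique(c(cr, pd))) == 1) 1 else
      wilcoxon_rank_sum(cr, pd)$p_value
    tibble(feature_id = f, platform = platform,
           overall = med_range(x), cr = med_range(cr), pd = med_range(pd),
           p_value = p, p_display = format_p(p))
  }) |> bind_rows()
}

write_report_tsv <- function(df, path, header) {
  df <- mutate(df, across(dplyr::where(is.list),
                          ~ map_chr(.x, paste, collapse = ",")))
  writeLines(c(header, sub("\n$", "", readr::format_tsv(df, na = "NA"))),
             path)
  path
}

#' Run the whole discovery pipeline and write a report bundle
#'
#' Simulates the cohort pair (or takes one supplied), runs the cascade,
#' computes risk scores, score ROCs and PD-anchored survival
#' stratifications in both arms, and writes TSV/JSON reports. Every file
#' carries a header line with the seed and config hash; identical
#' configurations produce byte-identical bundles.
#'
#' @param sim A [sim_config()], or a list `list(tr = , et = )` of cohorts.
#' @param config A [cascade_config()].
#' @param outdir Output directory.
#' @param anchor PD-anchor statistic for [dichotomize_by_pd()].
#' @return Invisibly, a list with the cohorts, cascade report, scores,
#'   ROCs, risk groups, survival tests and written file paths.
#' @export
run_pipeline <- function(sim = sim_config(), config = cascade_config(),
                         outdir, anchor = "mean") {
  if (inherits(sim, "sim_config")) {
    pair <- simulate_cohort_pair(sim)
    seed <- sim$seed
  } else {
    pair <- sim
    seed <- NA_integer_
  }
  tr <- pair$tr; et <- pair$et
  cascade <- run_cascade(tr, et, config)
  rules <- bind_rows(cascade$rna_rules, cascade$rppa_rules)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  header <- paste0("# crossres seed=", seed, " config=",
                   rlang::hash(list(sim, config, anchor)))
  paths <- character()
  emit <- function(df, name) {
    paths <<- c(paths, write_report_tsv(df, file.path(outdir, name), header))
  }

  emit(cascade$stages, "cascade_stages.tsv")
  result <- list(tr = tr, et = et, cascade = cascade)
  if (nrow(rules) > 0) {
    emit(rules, "panel_rules.tsv")
    scores_tr <- cumulative_score(tr, rules)
    scores_et <- cumulative_score(et, rules)
    emit(scores_tr, "scores_tr.tsv"); emit(scores_et, "scores_et.tsv")
    pd_ids <- tr$clinical$sample_id[tr$clinical$response == "PD"]

    score_cols <- c(rna = "rna_score", rppa = "rppa_score",
                    combined = "combined_score")
    score_cols <- score_cols[c(length(cascade$rna_panel) > 0,
                               length(cascade$rppa_panel %||% character()) > 0,
                               length(cascade$rna_panel) > 0 &&
                                 length(cascade$rppa_panel %||% character()) > 0)]
    labels_tr <- set_names(tr$clinical$response == "PD",
                           tr$clinical$sample_id)
    rocs <- imap(score_cols, function(col, nm) {
      keep <- !is.na(scores_tr[[col]])
      score_roc(scores_tr[[col]][keep],
                labels_tr[scores_tr$sample_id[keep]])
    })
    emit(bind_rows(imap(rocs, function(r, nm) {
      tibble(platform = nm, auc = r$auc, p_value = r$p_value,
             band = discrimination_band(r$auc),
             n_pos = r$n_pos, n_neg = r$n_neg)
    })), "score_roc.tsv")

    surv_rows <- list()
    groups_out <- list()
    for (nm in names(score_cols)) {
      col <- score_cols[[nm]]
      g_tr <- dichotomize_by_pd(scores_tr, pd_ids, anchor, score_col = col)
      g_et <- dichotomize_by_pd(scores_et, anchor = anchor, score_col = col,
                                threshold = g_tr$threshold)
      groups_out[[nm]] <- list(tr = g_tr, et = g_et)
      for (arm in c("tr", "et")) {
        g <- if (arm == "tr") g_tr else g_et
        ch <- if (arm == "tr") tr else et
        for (ep in c("PFS", "OS")) {
          st <- stratified_survival(g, ch, ep)
          surv_rows[[length(surv_rows) + 1]] <- tibble(
            platform = nm, arm = toupper(arm), endpoint = ep,
            threshold = g$threshold, chi_square = st$logrank$chi_square,
            p_value = st$logrank$p_value,
            p_display = format_p(st$logrank$p_value))
        }
      }
    }
    emit(bind_rows(surv_rows), "survival_stratification.tsv")
    if (all(c("rna", "rppa") %in% names(score_cols))) {
      emit(scatter_table(scores_tr, tr), "score_scatter_tr.tsv")
    }
    result <- c(result, list(scores_tr = scores_tr, scores_et = scores_et,
                             rocs = rocs, risk_groups = groups_out,
                             survival_tests = bind_rows(surv_rows)))
  }
  emit(baseline_table(tr), "baseline_tr.tsv")
  if (length(cascade$rna_panel) > 0) {
    emit(expression_summary_table(tr, cascade$rna_panel, "RNA"),
         "expression_rna.tsv")
  }
  if (length(cascade$rppa_panel %||% character()) > 0) {
    emit(expression_summary_table(tr, cascade$rppa_panel, "RPPA"),
         "expression_rppa.tsv")
  }
  summary <- list(
    seed = seed,
    n_tr = nrow(tr$clinical), n_et = nrow(et$clinical),
    rna_panel = cascade$rna_panel,
    rppa_panel = cascade$rppa_panel %||% character(),
    stage_counts = set_names(cascade$stages$n_output,
                             paste(cascade$stages$platform,
                                   cascade$stages$stage, sep = "_"))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, file.path(outdir, "summary.json"))
  result$paths <- paths
  invisible(result)
}
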