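#' Single-cutoff AUC from confusion counts
#'
#' The area under the one-point ROC curve through (1-specificity,
#' sensitivity): `TP/(2(TP+FN)) + TN/(2(FP+TN))`, i.e. the balanced
#' accuracy. `TP` counts high-risk subjects with the unfavored outcome and
#' `TN` low-risk subjects with the favored one.
#'
#' @param tp,fn,tn,fp Nonnegative counts; both outcome classes must be
#'   present (`tp + fn > 0`, `tn + fp > 0`). Vectorized.
#' @return AUC in `[0, 1]`.
#' @export
auc_single_cutoff <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) abort("counts must be nonnegative")
  if (any(tp + fn == 0) || any(tn + fp == 0)) {
    abort("both outcome classes must be present")
  }
  tp / (2 * (tp + fn)) + tn / (2 * (fp + tn))
}

#' Optimal cut-off rule for one feature
#'
#' Every observed value is tried as a cutoff under both directions
#' (`>= c` high-risk and `<= c` high-risk, boundary inclusive); the pair
#' maximizing the single-cutoff AUC is returned. Ties are broken
#' deterministically: higher sensitivity, then the cutoff farther from the
#' median value, then `>=` before `<=`. Because both directions are
#' searched, the returned AUC is always at least 0.5.
#'
#' @param values Per-sample feature values (missing values dropped).
#' @param outcome Logical, `TRUE` for the unfavored class (e.g. PD).
#' @param feature_id,platform Carried into the output row.
#' @return One-row tibble (a cutoff rule): `feature_id`, `platform`,
#'   `cutoff`, `direction` (`"ge"`/`"le"`), `response_iauc`, `sensitivity`,
#'   `specificity`.
#' @export
optimal_cutoff <- function(values, outcome, feature_id = NA_character_,
                           platform = NA_character_) {
  keep <- !is.na(values) & !is.na(outcome)
  values <- values[keep]; outcome <- as.logical(outcome[keep])
  if (length(unique(outcome)) < 2) abort("single outcome class")
  u <- sort(unique(values))
  if (length(u) < 2) abort("constant feature")
  cand <- cutoff_candidates(values, outcome, u)
  med <- median(values)
  cand <- mutate(cand,
                 auc = auc_single_cutoff(.data$tp, .data$fn, .data$tn, .data$fp),
                 sens = .data$tp / (.data$tp + .data$fn),
                 extremity = abs(.data$cutoff - med),
                 dir_rank = ifelse(.data$direction == "ge", 0L, 1L))
  best <- cand[order(-round(cand$auc, 12), -round(cand$sens, 12),
                     -round(cand$extremity, 12), cand$dir_rank), ][1, ]
  tibble(feature_id = feature_id, platform = platform,
         cutoff = best$cutoff, direction = best$direction,
         response_iauc = best$auc, sensitivity = best$sens,
         specificity = best$tn / (best$tn + best$fp))
}

# confusion counts for every (observed value, direction) candidate,
# via cumulative counts over the sorted unique values
cutoff_candidates <- function(values, outcome, u) {
  tab_all <- tabulate(match(values, u), nbins = length(u))
  tab_pos <- tabulate(match(values[outcome], u), nbins = length(u))
  p_tot <- sum(outcome); n_tot <- sum(!outcome)
  ge_all <- rev(cumsum(rev(tab_all))); ge_pos <- rev(cumsum(rev(tab_pos)))
  le_all <- cumsum(tab_all); le_pos <- cumsum(tab_pos)
  bind_rows(
    tibble(cutoff = u, direction = "ge", tp = ge_pos, fp = ge_all - ge_pos),
    tibble(cutoff = u, direction = "le", tp = le_pos, fp = le_all - le_pos)
  ) |>
    mutate(fn = p_tot - .data$tp, tn = n_tot - .data$fp)
}

#' Binary risk indicator under a cutoff rule
#'
#' A sample scores 1 when its value satisfies the rule's direction and
#' cutoff (inclusive). Missing values score 0 (low risk) so cumulative
#' scores stay comparable across samples; the number of missing values is
#' attached as attribute `n_missing`.
#'
#' @param values Numeric vector.
#' @param rule One-row rule tibble from [optimal_cutoff()].
#' @return Integer 0/1 vector.
#' @export
risk_indicator <- function(values, rule) {
  hit <- if (rule$direction == "ge") values >= rule$cutoff else values <= rule$cutoff
  out <- as.integer(hit & !is.na(values))
  attr(out, "n_missing") <- sum(is.na(values))
  out
}

#' Discrimination band of an AUC value
#'
#' `[0.7, 0.8)` acceptable, `[0.8, 0.9)` excellent, `[0.9, 1]` outstanding,
#' below 0.7 none; boundary values fall in the higher band.
#'
#' @param auc Numeric in `[0, 1]` (vectorized).
#' @return Character vector of band labels.
#' @export
discrimination_band <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) abort("auc must lie in [0, 1]")
  dplyr::case_when(auc >= 0.9 ~ "outstanding",
                   auc >= 0.8 ~ "excellent",
                   auc >= 0.7 ~ "acceptable",
                   TRUE ~ "none")
}

#' Fit cutoff rules for a set of features
#'
#' Runs [optimal_cutoff()] per feature against the CR/PD response of a
#' TR-arm cohort (PD = unfavored).
#'
#' @param cohort TR-arm [cohort()].
#' @param features Feature ids; default all features of the platform.
#' @param platform `"RNA"` or `"RPPA"`.
#' @return Tibble of rules (one row per feature), classed `cutoff_rules`.
#' @export
fit_cutoff_rules <- function(cohort, features = NULL,
                             platform = c("RNA", "RPPA")) {
  platform <- arg_match(platform)
  mat <- expr_matrix(cohort, platform)
  if (is.null(mat)) abort(paste("cohort carries no", platform, "matrix"))
  if (is.null(features)) features <- colnames(mat)
  cl <- cohort$clinical
  outcome <- set_names(cl$response == "PD", cl$sample_id)[rownames(mat)]
  rules <- map(features, function(f) {
    optimal_cutoff(mat[, f], outcome, feature_id = f, platform = platform)
  }) |> bind_rows()
  class(rules) <- c("cutoff_rules", class(rules))
  rules
}

#' Survival performance of a cutoff rule in a cohort
#'
#' Dichotomizes the cohort into high/low risk by [risk_indicator()] and
#' reports the single-cutoff AUC against the endpoint's event flag together
#' with the log-rank p-value between the risk groups (missing when a group
#' is empty).
#'
#' @param rule One-row rule tibble.
#' @param cohort A [cohort()].
#' @param endpoint `"PFS"` or `"OS"`.
#' @return One-row tibble: `feature_id`, `endpoint`, `arm`, `auc`,
#'   `p_value`, `n_high`, `n_low`.
#' @export
evaluate_rule_survival <- function(rule, cohort, endpoint = c("PFS", "OS")) {
  endpoint <- arg_match(endpoint)
  mat <- expr_matrix(cohort, rule$platform)
  if (is.null(mat) || !rule$feature_id %in% colnames(mat)) {
    abort(paste("feature", rule$feature_id, "not present in cohort"))
  }
  values <- mat[, rule$feature_id]
  ind <- risk_indicator(values, rule)
  cl <- cohort$clinical[match(rownames(mat), cohort$clinical$sample_id), ]
  time <- if (endpoint == "PFS") cl$pfs_time else cl$os_time
  event <- if (endpoint == "PFS") cl$pfs_event else cl$os_event
  tp <- sum(ind == 1 & event); fn <- sum(ind == 0 & event)
  tn <- sum(ind == 0 & !event); fp <- sum(ind == 1 & !event)
  auc <- if ((tp + fn) > 0 && (tn + fp) > 0) {
    auc_single_cutoff(tp, fn, tn, fp)
  } else NA_real_
  p <- if (all(c(sum(ind == 1), sum(ind == 0)) > 0)) {
    log_rank_test(time, event, ind)$p_value
  } else NA_real_
  tibble(feature_id = rule$feature_id, endpoint = endpoint,
         arm = cl$cohort_arm[1], auc = auc, p_value = p,
         n_high = sum(ind == 1), n_low = sum(ind == 0))
}

#' Annotate rules with survival metrics in both cohorts
#'
#' Adds, per rule, the PFS/OS single-cutoff AUC and log-rank p in the
#' derivation (TR) and validation (ET) cohorts — the layout of the
#' per-target rule tables the pipeline reports.
#'
#' @param rules A [fit_cutoff_rules()] tibble.
#' @param tr,et TR- and ET-arm [cohort()]s (`et` may be `NULL`).
#' @return `rules` with columns `tr_pfs_auc`, `tr_pfs_p`, `tr_os_auc`,
#'   `tr_os_p`, `et_pfs_auc`, `et_pfs_p`, `et_os_auc`, `et_os_p`.
#' @export
evaluate_rules <- function(rules, tr, et = NULL) {
  metric <- function(cohort, endpoint, col) {
    if (is.null(cohort)) return(rep(NA_real_, nrow(rules)))
    map_dbl(seq_len(nrow(rules)), function(i) {
      evaluate_rule_survival(rules[i, ], cohort, endpoint)[[col]]
    })
  }
  mutate(rules,
         tr_pfs_auc = metric(tr, "PFS", "auc"),
         tr_pfs_p = metric(tr, "PFS", "p_value"),
         tr_os_auc = metric(tr, "OS", "auc"),
         tr_os_p = metric(tr, "OS", "p_value"),
         et_pfs_auc = metric(et, "PFS", "auc"),
         et_pfs_p = metric(et, "PFS", "p_value"),
         et_os_auc = metric(et, "OS", "auc"),
         et_os_p = metric(et, "OS", "p_value"))
}
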