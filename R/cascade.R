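#' Configuration of the staged target-selection cascade
#'
#' Every threshold of the discovery workflow in one validated list. The
#' two-cohort consistency stage uses `strict_alpha` (default 0.05) for the
#' leading PFS condition of each criterion and `relaxed_alpha` (default
#' 0.10) for the trailing PFS/OS condition, mirroring the workflow's
#' "p <= 0.05 and p <= 0.1" criterion pairs.
#'
#' @param z_threshold Outlier screen |z| threshold.
#' @param survival_alpha Log-rank alpha for the PFS+OS significance filter.
#' @param fold_change_abs Minimum absolute group-mean difference (on the
#'   z-score scale) for the fold-change stage.
#' @param response_auc_min Minimum per-feature response AUC.
#' @param strict_alpha,relaxed_alpha Leading / trailing alphas of the
#'   consistency criteria.
#' @param tr_criteria,et_criteria Enabled criteria per arm (see
#'   [cohort_consistency_filter()]).
#' @param survival_dichotomy `"zflag"` dichotomizes by the |z| >= threshold
#'   outlier flag (default); `"rule"` uses the TR-derived optimal-cutoff
#'   rule.
#' @param panel_mode `"fixed"` grows greedy panels to the configured sizes
#'   (the sizes the reference workflow reports); `"improve"` stops as soon
#'   as no addition raises the response AUC.
#' @param rna_panel_size,rppa_panel_size Panel-size caps per platform.
#' @param min_fraction Passed to [flag_features()].
#' @return List of class `cascade_config`.
#' @export
cascade_config <- function(z_threshold = 2,
                           survival_alpha = 0.05,
                           fold_change_abs = 0.5,
                           response_auc_min = 0.6,
                           strict_alpha = 0.05,
                           relaxed_alpha = 0.10,
                           tr_criteria = c("auc", "pfs_et_pfs",
                                           "pfs_et_os", "pfs_os"),
                           et_criteria = c("pfs_tr_pfs", "pfs_tr_os",
                                           "pfs_os"),
                           survival_dichotomy = c("zflag", "rule"),
                           panel_mode = c("fixed", "improve"),
                           rna_panel_size = 10L,
                           rppa_panel_size = 5L,
                           min_fraction = NULL) {
  alphas <- c(survival_alpha, strict_alpha, relaxed_alpha)
  if (any(alphas <= 0) || any(alphas >= 1)) abort("alphas must lie in (0, 1)")
  if (z_threshold <= 0 || fold_change_abs < 0) abort("thresholds must be positive")
  structure(list(z_threshold = z_threshold, survival_alpha = survival_alpha,
                 fold_change_abs = fold_change_abs,
                 response_auc_min = response_auc_min,
                 strict_alpha = strict_alpha, relaxed_alpha = relaxed_alpha,
                 tr_criteria = tr_criteria, et_criteria = et_criteria,
                 survival_dichotomy = arg_match(survival_dichotomy),
                 panel_mode = arg_match(panel_mode),
                 rna_panel_size = as.integer(rna_panel_size),
                 rppa_panel_size = as.integer(rppa_panel_size),
                 min_fraction = min_fraction),
            class = "cascade_config")
}

#' Keep features whose outlier strata differ in both PFS and OS
#'
#' Each feature dichotomizes the cohort by its |z| >= threshold outlier
#' flag (or, with `survival_dichotomy = "rule"`, by a supplied cutoff
#' rule); the feature survives when the log-rank p-value is below
#' `survival_alpha` for both endpoints. Features with an empty stratum are
#' dropped with the reason recorded.
#'
#' @param features Feature ids present in the cohort's matrix.
#' @param cohort The [cohort()] providing expression and survival (the
#'   large ET arm in the standard workflow).
#' @param config A [cascade_config()].
#' @param platform Matrix to use.
#' @param rules Evaluated rules, required when
#'   `config$survival_dichotomy == "rule"`.
#' @return Character vector of surviving features, with a `detail`
#'   attribute tabulating per-feature p-values and drop reasons.
#' @export
survival_significance_filter <- function(features, cohort, config,
                                         platform = "RNA", rules = NULL) {
  if (length(features) == 0) return(empty_detail(character()))
  mat <- expr_matrix(cohort, platform)
  cl <- cohort$clinical[match(rownames(mat), cohort$clinical$sample_id), ]
  detail <- map(features, function(f) {
    if (config$survival_dichotomy == "rule") {
      if (is.null(rules) || !f %in% rules$feature_id) {
        abort(paste("no rule supplied for feature", f))
      }
      flag <- risk_indicator(mat[, f], rules[rules$feature_id == f, ]) == 1
    } else {
      flag <- abs(mat[, f]) >= config$z_threshold & !is.na(mat[, f])
    }
    if (all(flag) || !any(flag)) {
      return(tibble(feature_id = f, pfs_p = NA_real_, os_p = NA_real_,
                    kept = FALSE, reason = "empty stratum"))
    }
    pfs <- log_rank_test(cl$pfs_time, cl$pfs_event, flag)$p_value
    os <- log_rank_test(cl$os_time, cl$os_event, flag)$p_value
    kept <- pfs < config$survival_alpha && os < config$survival_alpha
    tibble(feature_id = f, pfs_p = pfs, os_p = os, kept = kept,
           reason = if (kept) "" else "p >= alpha")
  }) |> bind_rows()
  out <- detail$feature_id[detail$kept]
  attr(out, "detail") <- detail
  out
}

empty_detail <- function(x) {
  attr(x, "detail") <- tibble(feature_id = character(), pfs_p = double(),
                              os_p = double(), kept = logical(),
                              reason = character())
  x
}

#' Keep features differentiating either progressor arm from responders
#'
#' On z-scored (log-scale) expression a fold change is a difference of
#' group means; a feature survives when
#' `|mean(SERM/SERD PD) - mean(CR)|` or `|mean(AI PD) - mean(CR)|`
#' exceeds `fold_change_abs`.
#'
#' @inheritParams survival_significance_filter
#' @param tr TR-arm [cohort()] with regimen-annotated PD samples.
#' @return Surviving feature ids with a `detail` attribute of group-mean
#'   differences.
#' @export
fold_change_filter <- function(features, tr, config, platform = "RNA") {
  if (length(features) == 0) return(empty_detail(character()))
  mat <- expr_matrix(tr, platform)[, features, drop = FALSE]
  grp <- screen_groups(tr)[rownames(mat)]
  if (anyNA(grp)) abort("missing regimen annotation")
  gmean <- function(g) colMeans(mat[grp == g, , drop = FALSE], na.rm = TRUE)
  d_serm <- gmean("SERM_SERD_PD") - gmean("CR")
  d_ai <- gmean("AI_PD") - gmean("CR")
  kept <- abs(d_serm) > config$fold_change_abs |
    abs(d_ai) > config$fold_change_abs
  out <- features[kept]
  attr(out, "detail") <- tibble(feature_id = features,
                                diff_serm_serd = unname(d_serm),
                                diff_ai = unname(d_ai), kept = unname(kept))
  out
}

#' Two-cohort consistency filter over evaluated rules
#'
#' A feature survives when it satisfies at least one enabled TR-arm
#' criterion and at least one enabled ET-arm criterion. With `s` the strict
#' and `r` the relaxed alpha, the criteria are the conjunctions:
#'
#' * TR arm — `auc`: response AUC >= `response_auc_min`;
#'   `pfs_et_pfs`: TR PFS p <= s and ET PFS p <= r;
#'   `pfs_et_os`: TR PFS p <= s and ET OS p <= r;
#'   `pfs_os`: TR PFS p <= s and TR OS p <= r.
#' * ET arm — `pfs_tr_pfs`: ET PFS p <= s and TR PFS p <= r;
#'   `pfs_tr_os`: ET PFS p <= s and TR OS p <= r;
#'   `pfs_os`: ET PFS p <= s and ET OS p <= r.
#'
#' Missing p-values fail their condition.
#'
#' @param rules Rules evaluated in both cohorts ([evaluate_rules()]).
#' @param config A [cascade_config()].
#' @return Surviving feature ids with a `detail` attribute of per-criterion
#'   outcomes.
#' @export
cohort_consistency_filter <- function(rules, config) {
  if (length(config$tr_criteria) == 0 || length(config$et_criteria) == 0) {
    abort("no active criteria")
  }
  if (nrow(rules) == 0) return(empty_detail(character()))
  s <- config$strict_alpha; r <- config$relaxed_alpha
  le <- function(p, a) !is.na(p) & p <= a
  tr_ok <- list(
    auc = rules$response_iauc >= config$response_auc_min,
    pfs_et_pfs = le(rules$tr_pfs_p, s) & le(rules$et_pfs_p, r),
    pfs_et_os = le(rules$tr_pfs_p, s) & le(rules$et_os_p, r),
    pfs_os = le(rules$tr_pfs_p, s) & le(rules$tr_os_p, r)
  )[config$tr_criteria]
  et_ok <- list(
    pfs_tr_pfs = le(rules$et_pfs_p, s) & le(rules$tr_pfs_p, r),
    pfs_tr_os = le(rules$et_pfs_p, s) & le(rules$tr_os_p, r),
    pfs_os = le(rules$et_pfs_p, s) & le(rules$et_os_p, r)
  )[config$et_criteria]
  tr_any <- Reduce(`|`, tr_ok)
  et_any <- Reduce(`|`, et_ok)
  kept <- tr_any & et_any
  out <- rules$feature_id[kept]
  attr(out, "detail") <- tibble(feature_id = rules$feature_id,
                                tr_arm_ok = tr_any, et_arm_ok = et_any,
                                kept = kept)
  out
}

#' Greedy cumulative-ROC panel selection
#'
#' Builds an ordered panel by forward selection: at each step the feature
#' whose inclusion maximizes the Mann-Whitney AUC of the cumulative risk
#' score against the CR/PD response is added (ties: higher PFS AUC of the
#' cumulative score, then alphabetical feature id). In `"improve"` mode the
#' selection stops when no addition strictly raises the response AUC; in
#' `"fixed"` mode it continues to `max_size`.
#'
#' @param rules Candidate rules (one row per feature) from
#'   [fit_cutoff_rules()].
#' @param tr TR-arm [cohort()].
#' @param config A [cascade_config()] (supplies the mode).
#' @param platform Matrix the rules refer to.
#' @param max_size Panel-size cap; defaults to the platform's configured
#'   size.
#' @return Tibble of class `panel_selection`: `step`, `feature_id`,
#'   `response_auc` (trajectory after each addition); the ordered panel is
#'   in attribute `panel`.
#' @export
cumulative_panel_selection <- function(rules, tr, config = cascade_config(),
                                       platform = "RNA", max_size = NULL) {
  if (nrow(rules) == 0) abort("empty candidate list")
  if (is.null(max_size)) {
    max_size <- if (platform == "RNA") config$rna_panel_size else
      config$rppa_panel_size
  }
  mat <- expr_matrix(tr, platform)
  cl <- tr$clinical[match(rownames(mat), tr$clinical$sample_id), ]
  labels <- cl$response == "PD"
  ind <- vapply(seq_len(nrow(rules)), function(i) {
    risk_indicator(mat[, rules$feature_id[i]], rules[i, ])
  }, integer(nrow(mat)))
  colnames(ind) <- rules$feature_id

  selected <- character()
  score <- rep(0L, nrow(mat))
  auc_now <- -Inf
  trajectory <- list()
  remaining <- sort(rules$feature_id)
  while (length(selected) < max_size && length(remaining) > 0) {
    stats <- map(remaining, function(f) {
      s <- score + ind[, f]
      tibble(feature_id = f,
             auc = mw_auc(s, labels),
             pfs_auc = mw_auc(s, cl$pfs_event))
    }) |> bind_rows()
    stats <- stats[order(-round(stats$auc, 12), -round(stats$pfs_auc, 12),
                         stats$feature_id), ]
    best <- stats[1, ]
    if (config$panel_mode == "improve" && best$auc <= auc_now + 1e-12) break
    selected <- c(selected, best$feature_id)
    score <- score + ind[, best$feature_id]
    auc_now <- best$auc
    trajectory[[length(selected)]] <-
      tibble(step = length(selected), feature_id = best$feature_id,
             response_auc = best$auc)
    remaining <- setdiff(remaining, best$feature_id)
  }
  out <- bind_rows(trajectory)
  if (nrow(out) == 0) {
    out <- tibble(step = integer(), feature_id = character(),
                  response_auc = double())
  }
  class(out) <- c("panel_selection", class(out))
  attr(out, "panel") <- selected
  out
}

#' Run the full discovery cascade on a cohort pair
#'
#' RNA path: outlier screen on the TR arm, Venn candidate region (features
#' flagged in both progressor arms), PFS+OS significance filter in the ET
#' arm, fold-change filter versus CR, two-cohort consistency filter over
#' fitted cutoff rules, and greedy cumulative-ROC panel selection. RPPA
#' path: screen, candidate region and panel selection directly (the protein
#' candidates are retained without the intermediate filters). Deterministic
#' given cohorts and config.
#'
#' @param tr,et TR- and ET-arm [cohort()]s.
#' @param config A [cascade_config()].
#' @return Object of class `cascade_report`: `stages` (per-stage audit
#'   tibble with feature list-column), `rna_panel`, `rppa_panel`,
#'   `rna_rules`, `rppa_rules` (evaluated rule tables for the panels),
#'   `config`.
#' @export
run_cascade <- function(tr, et, config = cascade_config()) {
  stages <- list()
  note <- function(platform, stage, input, output, criteria) {
    stages[[length(stages) + 1]] <<- tibble(
      platform = platform, stage = stage,
      n_input = length(input), n_output = length(output),
      criteria = criteria, features = list(as.character(output)))
  }

  run_platform <- function(platform, full_filters) {
    all_features <- colnames(expr_matrix(tr, platform))
    flags <- flag_features(tr, screen_groups(tr), config$z_threshold,
                           config$min_fraction, platform = platform)
    part <- venn_partition(flags)
    cands <- candidate_region(part)
    note(platform, "venn_candidates", all_features, cands,
         paste0("|z| >= ", config$z_threshold, " in both PD arms"))
    if (full_filters) {
      surv <- survival_significance_filter(cands, et, config, platform)
      note(platform, "pfs_os_significance", cands, surv,
           paste0("log-rank p < ", config$survival_alpha, " for PFS and OS"))
      fc <- fold_change_filter(surv, tr, config, platform)
      note(platform, "fold_change", surv, fc,
           paste0("|group-mean diff vs CR| > ", config$fold_change_abs))
      cands <- fc
    }
    if (length(cands) == 0) {
      note(platform, "panel", cands, character(), "greedy cumulative ROC")
      return(list(panel = character(), rules = NULL))
    }
    rules <- fit_cutoff_rules(tr, cands, platform)
    rules <- evaluate_rules(rules, tr, et)
    if (full_filters) {
      cons <- cohort_consistency_filter(rules, config)
      note(platform, "cohort_consistency", cands, cons,
           "one TR-arm and one ET-arm criterion")
      rules <- rules[rules$feature_id %in% cons, ]
      cands <- cons
    }
    if (length(cands) == 0) {
      note(platform, "panel", cands, character(), "greedy cumulative ROC")
      return(list(panel = character(), rules = rules))
    }
    sel <- cumulative_panel_selection(rules, tr, config, platform)
    panel <- attr(sel, "panel")
    note(platform, "panel", cands, panel,
         paste0("greedy cumulative ROC (", config$panel_mode, ")"))
    list(panel = panel, rules = rules[match(panel, rules$feature_id), ],
         trajectory = sel)
  }

  rna <- run_platform("RNA", full_filters = TRUE)
  rppa <- if (!is.null(tr$rppa)) run_platform("RPPA", full_filters = FALSE)

  structure(list(stages = bind_rows(stages),
                 rna_panel = rna$panel, rna_rules = rna$rules,
                 rna_trajectory = rna$trajectory,
                 rppa_panel = rppa$panel, rppa_rules = rppa$rules,
                 rppa_trajectory = rppa$trajectory,
                 config = config),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(select(x$stages, -"features"))
  cat("RNA panel:", paste(x$rna_panel, collapse = ", "), "\n")
  if (!is.null(x$rppa_panel)) {
    cat("RPPA panel:", paste(x$rppa_panel, collapse = ", "), "\n")
  }
  invisible(x)
}
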