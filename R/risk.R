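# Mann-Whitney AUC with ties (midrank formulation); NA for a single class
mw_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cumulative risk scores from per-feature cutoff rules
#'
#' Each sample's platform score is the number of panel features on whose
#' high-risk side it falls; the combined score adds the RNA and RPPA scores
#' where both exist. Samples without RPPA measurements get an RNA-only
#' score and a missing combined score.
#'
#' @param cohort A [cohort()].
#' @param rules Rule table covering one or both platforms (`platform`
#'   column distinguishes them).
#' @return Tibble: `sample_id`, `rna_score`, `rppa_score`,
#'   `combined_score`.
#' @export
cumulative_score <- function(cohort, rules) {
  if (nrow(rules) == 0) abort("empty panel")
  platform_score <- function(platform) {
    sub <- rules[rules$platform == platform, ]
    mat <- expr_matrix(cohort, platform)
    if (nrow(sub) == 0 || is.null(mat)) return(NULL)
    missing_feats <- setdiff(sub$feature_id, colnames(mat))
    if (length(missing_feats) > 0) {
      abort(paste("rules reference absent features:",
                  paste(missing_feats, collapse = ", ")))
    }
    s <- rowSums(vapply(seq_len(nrow(sub)), function(i) {
      risk_indicator(mat[, sub$feature_id[i]], sub[i, ])
    }, integer(nrow(mat))))
    set_names(as.integer(s), rownames(mat))
  }
  rna <- platform_score("RNA")
  rppa <- platform_score("RPPA")
  ids <- cohort$clinical$sample_id
  out <- tibble(sample_id = ids,
                rna_score = if (is.null(rna)) NA_integer_ else
                  unname(rna[ids]),
                rppa_score = if (is.null(rppa)) NA_integer_ else
                  unname(rppa[ids]))
  mutate(out, combined_score = .data$rna_score + .data$rppa_score)
}

#' ROC curve of an integer risk score against CR/PD labels
#'
#' Empirical ROC over the score thresholds; the AUC uses the rank
#' (Mann-Whitney) formulation with midranks for ties, and the p-value tests
#' AUC = 0.5 by the tie-corrected normal approximation of the Mann-Whitney
#' statistic.
#'
#' @param scores Per-sample scores.
#' @param labels Logical (or coercible), `TRUE` for the unfavored class.
#' @return Object of class `score_roc`: `curve` (threshold, sensitivity,
#'   specificity), `auc`, `p_value`, `n_pos`, `n_neg`.
#' @export
score_roc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both label classes must be present")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  curve <- map(thresholds, function(t) {
    call_pos <- scores >= t
    tibble(threshold = t,
           sensitivity = sum(call_pos & labels) / n1,
           specificity = sum(!call_pos & !labels) / n0)
  }) |> bind_rows()
  curve <- bind_rows(tibble(threshold = Inf, sensitivity = 0, specificity = 1),
                     curve,
                     tibble(threshold = -Inf, sensitivity = 1, specificity = 0))
  auc <- mw_auc(scores, labels)
  n <- n1 + n0
  ties <- table(scores)
  u <- auc * n1 * n0
  v <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (v <= 0) 1 else 2 * pnorm(-abs((u - n1 * n0 / 2) / sqrt(v)))
  structure(list(curve = curve, auc = auc, p_value = p,
                 n_pos = n1, n_neg = n0),
            class = "score_roc")
}

#' @export
print.score_roc <- function(x, ...) {
  cat("<score_roc> AUC =", round(x$auc, 3),
      paste0("(", discrimination_band(x$auc), ")"),
      "p =", format.pval(x$p_value, digits = 3),
      "| n =", x$n_pos, "pos /", x$n_neg, "neg\n")
  invisible(x)
}

#' Dichotomize a cohort at the PD-anchored score threshold
#'
#' The high/low-risk threshold is the mean or median cumulative score of
#' the PD samples, rounded up when fractional (for integer scores,
#' "score >= mean" is the same as "score >= ceiling(mean)"). The ET cohort
#' reuses a TR-derived threshold unchanged by passing `threshold` directly.
#'
#' @param scores Tibble from [cumulative_score()] or named numeric vector.
#' @param pd_samples Sample ids of the PD anchor group (ignored when
#'   `threshold` is given).
#' @param anchor `"mean"` or `"median"` of the PD scores.
#' @param score_col Which score column to use when `scores` is a tibble.
#' @param threshold Optional pre-derived integer threshold to reuse.
#' @return Object of class `risk_groups`: `threshold`, `anchor`,
#'   `assignment` tibble (`sample_id`, `score`, `risk` = "high"/"low";
#'   samples with missing scores are excluded).
#' @export
dichotomize_by_pd <- function(scores, pd_samples = NULL,
                              anchor = c("mean", "median"),
                              score_col = "combined_score",
                              threshold = NULL) {
  anchor <- arg_match(anchor)
  if (is.data.frame(scores)) {
    scores <- set_names(scores[[score_col]], scores$sample_id)
  }
  scores <- scores[!is.na(scores)]
  if (is.null(threshold)) {
    pd <- scores[names(scores) %in% pd_samples]
    if (length(pd) == 0) abort("empty PD anchor set")
    threshold <- ceiling(if (anchor == "mean") mean(pd) else median(pd))
  }
  structure(list(threshold = threshold, anchor = anchor,
                 assignment = tibble(sample_id = names(scores),
                                     score = unname(scores),
                                     risk = ifelse(scores >= threshold,
                                                   "high", "low"))),
            class = "risk_groups")
}

#' @export
print.risk_groups <- function(x, ...) {
  tab <- table(x$assignment$risk)
  cat("<risk_groups> score >=", x$threshold, "(", x$anchor, "anchor ):",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Kaplan-Meier stratification by risk group
#'
#' @param groups A [dichotomize_by_pd()] result.
#' @param cohort The [cohort()] the samples belong to.
#' @param endpoint `"PFS"` or `"OS"`.
#' @return Object of class `stratified_survival`: `km` (per-group KM step
#'   data), `logrank` (one-row tibble; p missing when a group is empty),
#'   `endpoint`.
#' @export
stratified_survival <- function(groups, cohort, endpoint = c("PFS", "OS")) {
  endpoint <- arg_match(endpoint)
  cl <- left_join(groups$assignment, cohort$clinical, by = "sample_id")
  time <- if (endpoint == "PFS") cl$pfs_time else cl$os_time
  event <- if (endpoint == "PFS") cl$pfs_event else cl$os_event
  km <- map(unique(cl$risk), function(g) {
    sel <- cl$risk == g
    mutate(km_estimate(time[sel], event[sel]), risk = g)
  }) |> bind_rows()
  lr <- if (length(unique(cl$risk)) == 2) {
    log_rank_test(time, event, cl$risk)
  } else {
    tibble(chi_square = NA_real_, df = 1L, p_value = NA_real_)
  }
  structure(list(km = km, logrank = lr, endpoint = endpoint),
            class = "stratified_survival")
}

#' @export
print.stratified_survival <- function(x, ...) {
  cat("<stratified_survival>", x$endpoint,
      "log-rank p =", format.pval(x$logrank$p_value, digits = 3), "\n")
  invisible(x)
}

#' Plot-ready RNA x RPPA risk-score scatter table
#'
#' @param scores Tibble from [cumulative_score()].
#' @param labels Named vector (sample id -> label, e.g. response), or a
#'   [cohort()] from which the response labels are taken.
#' @return Tibble `sample_id`, `rna_score`, `rppa_score`, `label`;
#'   samples missing either platform are excluded and their count attached
#'   as attribute `n_excluded` (with a warning when everything is
#'   excluded).
#' @export
scatter_table <- function(scores, labels) {
  if (inherits(labels, "crossres_cohort")) {
    labels <- set_names(labels$clinical$response, labels$clinical$sample_id)
  }
  out <- scores |>
    mutate(label = unname(labels[.data$sample_id])) |>
    select("sample_id", "rna_score", "rppa_score", "label")
  keep <- !is.na(out$rna_score) & !is.na(out$rppa_score)
  excluded <- sum(!keep)
  out <- out[keep, ]
  if (nrow(out) == 0) warn("no samples carry both platform scores")
  attr(out, "n_excluded") <- excluded
  out
}
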