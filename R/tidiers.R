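#' Tidy a feature-flag screen
#'
#' @param x A [flag_features()] result.
#' @param ... Unused.
#' @return Tibble with one row per (group, feature).
#' @export
tidy.feature_flags <- function(x, ...) {
  bind_rows(imap(x$sets, ~ tibble(group = .y, feature_id = .x)))
}

#' @rdname tidy.feature_flags
#' @export
tidy.venn_partition <- function(x, ...) {
  bind_rows(imap(x$regions, ~ tibble(region = .y, feature_id = .x)))
}

#' @rdname tidy.feature_flags
#' @export
glance.venn_partition <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' Tidy a correlation matrix into feature pairs
#'
#' @param x A [pearson_matrix()] result.
#' @param ... Unused.
#' @return Tibble `feature_1`, `feature_2`, `r`, `p_value`, `n` over the
#'   upper triangle.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(feature_1 = x$feature_ids[idx[, 1]],
         feature_2 = x$feature_ids[idx[, 2]],
         r = x$r[idx], p_value = x$p[idx], n = x$n[idx])
}

#' Tidy and summarise a score ROC
#'
#' @param x A [score_roc()] object.
#' @param ... Unused.
#' @return `tidy()`: the ROC curve points; `glance()`: one row with `auc`,
#'   `p_value`, band and class sizes.
#' @export
tidy.score_roc <- function(x, ...) x$curve

#' @rdname tidy.score_roc
#' @export
glance.score_roc <- function(x, ...) {
  tibble(auc = x$auc, p_value = x$p_value,
         band = discrimination_band(x$auc),
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a cascade report
#'
#' @param x A [run_cascade()] report.
#' @param ... Unused.
#' @return `tidy()`: one row per stage and surviving feature; `glance()`:
#'   the per-stage counts in wide form.
#' @export
tidy.cascade_report <- function(x, ...) {
  tidyr::unnest(select(x$stages, "platform", "stage", "features"),
                "features") |>
    rename(feature_id = "features")
}

#' @rdname tidy.cascade_report
#' @export
glance.cascade_report <- function(x, ...) {
  tibble(rna_candidates =
           x$stages$n_output[x$stages$platform == "RNA"][1],
         rna_panel_size = length(x$rna_panel),
         rppa_panel_size = length(x$rppa_panel %||% character()),
         panel_mode = x$config$panel_mode)
}

#' Tidy risk-group assignments and stratified survival
#'
#' @param x A [dichotomize_by_pd()] or [stratified_survival()] object.
#' @param ... Unused.
#' @return Tibbles mirroring the underlying assignment / KM step data.
#' @export
tidy.risk_groups <- function(x, ...) x$assignment

#' @rdname tidy.risk_groups
#' @export
glance.risk_groups <- function(x, ...) {
  tab <- table(x$assignment$risk)
  tibble(threshold = x$threshold, anchor = x$anchor,
         n_high = sum(x$assignment$risk == "high"),
         n_low = sum(x$assignment$risk == "low"))
}

#' @rdname tidy.risk_groups
#' @export
tidy.stratified_survival <- function(x, ...) x$km

#' @rdname tidy.risk_groups
#' @export
glance.stratified_survival <- function(x, ...) {
  mutate(x$logrank, endpoint = x$endpoint)
}
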