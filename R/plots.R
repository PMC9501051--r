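#' @importFrom ggplot2 ggplot aes geom_step geom_point geom_abline geom_col
#'   geom_line labs theme_minimal coord_equal facet_wrap position_dodge
NULL

#' ROC curve plot
#'
#' @param object A [score_roc()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.score_roc <- function(object, ...) {
  d <- mutate(object$curve, fpr = 1 - .data$specificity)
  ggplot(d, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, colour = "red", linetype = 2) +
    geom_step(direction = "hv") +
    geom_point(size = 1) +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("Risk-score ROC (AUC = %.3f, p = %s)",
                         object$auc, format_p(object$p_value))) +
    theme_minimal()
}

#' Kaplan-Meier plot of a risk stratification
#'
#' @param object A [stratified_survival()] object.
#' @param ... Unused.
#' @return A ggplot with one step curve per risk group and censor ticks.
#' @export
autoplot.stratified_survival <- function(object, ...) {
  km <- object$km
  starts <- distinct(km, .data$risk) |>
    mutate(time = 0, surv = 1, n_censor = 0)
  d <- bind_rows(starts, km) |> arrange(.data$risk, .data$time)
  ggplot(d, aes(x = .data$time, y = .data$surv, colour = .data$risk)) +
    geom_step() +
    geom_point(data = filter(d, .data$n_censor > 0), shape = 3) +
    labs(x = "Time (days)", y = "Survival probability",
         title = sprintf("%s by risk group (log-rank p = %s)",
                         object$endpoint, format_p(object$logrank$p_value))) +
    theme_minimal()
}

#' Cascade attrition plot
#'
#' @param object A [run_cascade()] report.
#' @param ... Unused.
#' @return A ggplot of surviving-feature counts per stage and platform.
#' @export
autoplot.cascade_report <- function(object, ...) {
  d <- mutate(object$stages,
              stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot(d, aes(x = .data$stage, y = .data$n_output,
                fill = .data$platform)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "Surviving features") +
    theme_minimal()
}

#' RNA x RPPA risk-score scatter plot
#'
#' @param scatter A [scatter_table()] tibble.
#' @return A ggplot; points are jittered slightly because scores are
#'   integers.
#' @export
plot_score_scatter <- function(scatter) {
  ggplot(scatter, aes(x = .data$rna_score, y = .data$rppa_score,
                      colour = .data$label)) +
    ggplot2::geom_jitter(width = 0.12, height = 0.12, alpha = 0.8) +
    labs(x = "RNA cumulative risk score", y = "RPPA cumulative risk score") +
    theme_minimal()
}
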