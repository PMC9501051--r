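#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper with the conventions used throughout the reports: exact
#' enumeration when the combined sample size is at most `exact_max` and the
#' data are tie-free, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param exact_max Combined-size threshold for the exact test (default 20).
#' @return One-row tibble: `statistic` (rank-sum U), `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) abort("each group needs >= 1 observation")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         method = if (exact) "wilcoxon-exact" else "wilcoxon-normal",
         n_x = length(x), n_y = length(y))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the probability-mass ordering: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (within a 1e-7
#' relative tolerance, the convention of common statistical software). The
#' table rows are the two groups: group 1 has `a` positives and `b`
#' negatives, group 2 has `c` and `d`. A zero margin makes the table
#' degenerate and returns p = 1.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return One-row tibble: `statistic` (observed count `a`), `p_value`,
#'   `method`, `n_x`, `n_y` (group sizes).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be nonnegative integers")
  }
  tibble::new_tibble(list(statistic = a, p_value = fisher_p2(a, b, c, d),
                          method = "fisher-exact", n_x = a + b, n_y = c + d),
                     nrow = 1L)
}

# vectorised over observed a for a fixed margin set; used by the exhaustive
# enumeration tests as well as fisher_exact_2x2
fisher_p2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- probs[support == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Kruskal-Wallis rank-sum test across two or more groups
#'
#' @param groups List of two or more nonempty numeric samples.
#' @return One-row tibble: tie-corrected `statistic` (H), `p_value` from the
#'   chi-square reference, `method`, `n_x` = total n, `n_y` = number of
#'   groups. All values identical across groups yields H = 0, p = 1.
#' @export
kruskal_wallis <- function(groups) {
  groups <- map(groups, ~ .x[!is.na(.x)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need >= 2 nonempty groups")
  }
  values <- unlist(groups)
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, p_value = 1, method = "kruskal-wallis",
                  n_x = length(values), n_y = length(groups)))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- kruskal.test(values, g)
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         method = "kruskal-wallis", n_x = length(values),
         n_y = length(groups))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Nonnegative follow-up durations (days).
#' @param events Logical event indicators (censoring handled by the standard
#'   event-first convention at tied times).
#' @return A tibble of class `km_curve` over the distinct observed times:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("empty input")
  if (length(times) != length(events)) abort("times and events differ in length")
  if (any(times < 0)) abort("times must be nonnegative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard Mantel-Haenszel log-rank statistic with the discrete-time
#' hypergeometric variance at tied times, 1 degree of freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Two-level group labels, both levels nonempty.
#' @return One-row tibble: `chi_square`, `df`, `p_value`.
#' @export
log_rank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) abort("need exactly two nonempty groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  tibble(chi_square = fit$chisq, df = 1L,
         p_value = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson coefficients with two-sided t-test p-values.
#' Constant features (or pairs with fewer than 3 complete samples) are
#' recorded as missing.
#'
#' @param values Numeric matrix, samples in rows, features in columns; or a
#'   [cohort()] together with `platform`.
#' @param features Optional character subset of feature columns.
#' @param platform Used when `values` is a cohort.
#' @return List of class `correlation_matrix`: `feature_ids`, `r`, `p`, `n`.
#' @export
pearson_matrix <- function(values, features = NULL, platform = "RNA") {
  if (inherits(values, "crossres_cohort")) {
    values <- expr_matrix(values, platform)
  }
  if (!is.null(features)) values <- values[, features, drop = FALSE]
  r <- suppressWarnings(cor(values, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(values))
  t_stat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = pmax(n - 2, 1))
  p[n < 3] <- NA_real_
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  structure(list(feature_ids = colnames(values), r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>", length(x$feature_ids), "features\n")
  off <- x$r[upper.tri(x$r)]
  cat("  off-diagonal r: median", round(median(off, na.rm = TRUE), 3),
      "range", paste(round(range(off, na.rm = TRUE), 3), collapse = " to "),
      "\n")
  invisible(x)
}
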