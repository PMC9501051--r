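# Small, slow, self-evident reference implementations used to check the
# package's fast paths. They share no code with the implementation.

# exhaustive search over every (observed value, direction) cutoff candidate
brute_force_cutoff <- function(values, outcome) {
  best <- list(auc = -Inf)
  for (c in unique(values)) {
    for (dir in c("ge", "le")) {
      high <- if (dir == "ge") values >= c else values <= c
      tp <- sum(high & outcome); fn <- sum(!high & outcome)
      tn <- sum(!high & !outcome); fp <- sum(high & !outcome)
      auc <- tp / (2 * (tp + fn)) + tn / (2 * (fp + tn))
      if (auc > best$auc + 1e-12) {
        best <- list(auc = auc, cutoff = c, direction = dir)
      }
    }
  }
  best
}

# two-sided Fisher p by direct probability enumeration with choose()
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  aa <- max(0, k - n):min(k, m)
  pr <- choose(m, aa) * choose(n, k - aa) / choose(m + n, k)
  obs <- pr[aa == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# trapezoidal integration of the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- sapply(th, function(t) mean(scores[labels] >= t))
  fpr <- sapply(th, function(t) mean(scores[!labels] >= t))
  sens <- c(sens, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# textbook Mantel-Haenszel log-rank chi-square, looping event times
plain_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group)) == 1
  o_e <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# small synthetic configs keep the unit suite fast
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_et = 60,
                                 n_rna_features = 60, n_rppa_features = 20),
                            list(...))
  do.call(sim_config, args)
}

# hand-built 6-sample TR cohort used by the io tests
tiny_cohort <- function() {
  clinical <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:6),
    cohort_arm = "TR",
    response = c("CR", "CR", "CR", "CR", "PD", "PD"),
    regimen = c("AI", "SERM", "AI", "SERD", "AI", "SERM"),
    age_years = c(55, 60, 48, 71, 66, 59),
    t_stage = c("T1_2", "T1_2", "T3_4", "T1_2", "T1_2", "T3_4"),
    n_stage = c("N0", "N1_3", "N0", "N0", "N1_3", "N1_3"),
    m_stage = c("M0", "M0", "M0", "M0", "M1", "M0"),
    stage = c("I_II", "I_II", "III_IV", "I_II", "III_IV", "III_IV"),
    pfs_time = c(900, 1200, 800, 1500, 300, 200),
    pfs_event = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    os_time = c(900, 1300, 1000, 1500, 400, 350),
    os_event = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  rna <- matrix(round(rnorm(6 * 4), 3), 6, 4,
                dimnames = list(clinical$sample_id, paste0("G", 1:4)))
  rppa <- matrix(round(rnorm(4 * 2), 3), 4, 2,
                 dimnames = list(clinical$sample_id[1:4], paste0("P", 1:2)))
  rppa[2, 1] <- NA
  cohort(clinical, rna, rppa)
}
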