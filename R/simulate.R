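#' Simulation settings for the two-arm synthetic cohorts
#'
#' The generator emulates the structure the discovery pipeline assumes: a
#' small treatment-response (TR) cohort with CR/PD labels whose progressors
#' split evenly between the AI and SERM/SERD regimens, a large
#' endocrine-therapy (ET) cohort without response labels but with a latent
#' resistance indicator, correlated feature blocks on the z-score scale,
#' planted resistance markers shifted by `effect_shift` in resistant
#' samples, an RPPA matrix carried by a subset of samples, and censored
#' exponential PFS/OS worse in resistant samples.
#'
#' @param seed Integer seed driving every draw.
#' @param n_cr,n_pd,n_et Cohort sizes: responders and progressors in the TR
#'   arm, samples in the ET arm.
#' @param n_rna_features,n_rppa_features Number of features per platform.
#' @param n_informative_rna,n_informative_rppa Number of planted resistance
#'   markers per platform.
#' @param effect_shift Mean z-score shift of planted markers in resistant
#'   samples (unit variance throughout).
#' @param block_size,block_rho Correlation blocks: features come in
#'   equicorrelated blocks of `block_size` with within-block correlation
#'   `block_rho`; planted markers are spread one per block so the
#'   correlation-matrix stage has structure to find.
#' @param arm_mix Named probabilities over regimens `AI`, `SERM`, `SERD`.
#' @param baseline_hazard Baseline PFS hazard per day (OS hazard is half of
#'   it); default 1/1200 puts the median progression time near 2.3 years.
#' @param hazard_ratio_pd PFS/OS hazard multiplier for resistant samples.
#' @param censor_rate Target probability that a subject is censored, met by
#'   independent exponential censoring.
#' @param et_resistance_prevalence Latent resistance prevalence in the ET
#'   arm.
#' @param rppa_subset_fraction Fraction of TR samples carrying RPPA
#'   (default 32/44, applied to both arms, stratified by response).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cr = 34L, n_pd = 10L, n_et = 449L,
                       n_rna_features = 500L, n_rppa_features = 100L,
                       n_informative_rna = 10L, n_informative_rppa = 5L,
                       effect_shift = 1.5,
                       block_size = 10L, block_rho = 0.5,
                       arm_mix = c(AI = 0.50, SERM = 0.45, SERD = 0.05),
                       baseline_hazard = 1 / 1200,
                       hazard_ratio_pd = 2.5,
                       censor_rate = 0.3,
                       et_resistance_prevalence = 0.15,
                       rppa_subset_fraction = 32 / 44) {
  cfg <- list(seed = as.integer(seed),
              n_cr = as.integer(n_cr), n_pd = as.integer(n_pd),
              n_et = as.integer(n_et),
              n_rna_features = as.integer(n_rna_features),
              n_rppa_features = as.integer(n_rppa_features),
              n_informative_rna = as.integer(n_informative_rna),
              n_informative_rppa = as.integer(n_informative_rppa),
              effect_shift = effect_shift,
              block_size = as.integer(block_size), block_rho = block_rho,
              arm_mix = arm_mix,
              baseline_hazard = baseline_hazard,
              hazard_ratio_pd = hazard_ratio_pd,
              censor_rate = censor_rate,
              et_resistance_prevalence = et_resistance_prevalence,
              rppa_subset_fraction = rppa_subset_fraction)
  counts <- c(cfg$n_cr, cfg$n_pd, cfg$n_et,
              cfg$n_rna_features, cfg$n_rppa_features, cfg$block_size)
  if (any(counts <= 0)) abort("all counts must be positive")
  if (cfg$n_informative_rna > cfg$n_rna_features ||
      cfg$n_informative_rppa > cfg$n_rppa_features) {
    abort("infeasible config: n_informative exceeds n_features")
  }
  if (abs(cfg$block_rho) > 1) abort("block_rho must lie in [-1, 1]")
  probs <- c(cfg$arm_mix, cfg$censor_rate, cfg$et_resistance_prevalence,
             cfg$rppa_subset_fraction)
  if (any(probs < 0) || any(probs > 1)) abort("probabilities must lie in [0, 1]")
  if (!setequal(names(cfg$arm_mix), c("AI", "SERM", "SERD"))) {
    abort("arm_mix must name AI, SERM and SERD")
  }
  cfg$arm_mix <- cfg$arm_mix[c("AI", "SERM", "SERD")] / sum(cfg$arm_mix)
  if (cfg$baseline_hazard <= 0 || cfg$hazard_ratio_pd <= 0) {
    abort("hazards must be positive")
  }
  structure(cfg, class = "sim_config")
}

# deterministic placement: marker i sits at the head of block i (spread
# across blocks while they last, then consecutively)
informative_indices <- function(n_features, n_informative, block_size) {
  n_blocks <- ceiling(n_features / block_size)
  if (n_informative <= n_blocks) {
    (seq_len(n_informative) - 1L) * block_size + 1L
  } else {
    seq_len(n_informative)
  }
}

feature_ids <- function(platform, n) {
  prefix <- if (platform == "RNA") "G" else "P"
  sprintf("%s%04d", prefix, seq_len(n))
}

#' Planted truth of the generator's features
#'
#' Returns, for every feature the generator would emit under `config`,
#' whether it is a planted resistance marker and its mean shift in resistant
#' samples. Intended as a test oracle; no random draws are involved.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `feature_id`, `platform`, `informative`,
#'   `delta`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  one <- function(platform, n, n_inf) {
    ids <- feature_ids(platform, n)
    idx <- informative_indices(n, n_inf, config$block_size)
    tibble(feature_id = ids, platform = platform,
           informative = seq_len(n) %in% idx,
           delta = ifelse(seq_len(n) %in% idx, config$effect_shift, 0))
  }
  bind_rows(one("RNA", config$n_rna_features, config$n_informative_rna),
            one("RPPA", config$n_rppa_features, config$n_informative_rppa))
}

# equicorrelated block-Gaussian noise, unit marginal variance
block_noise <- function(n, n_features, block_size, rho) {
  x <- matrix(rnorm(n * n_features), n, n_features)
  if (rho == 0) return(x)
  blocks <- split(seq_len(n_features),
                  ceiling(seq_len(n_features) / block_size))
  for (idx in blocks) {
    shared <- rnorm(n)
    x[, idx] <- sqrt(abs(rho)) * shared + sqrt(1 - abs(rho)) * x[, idx]
    if (rho < 0 && length(idx) > 1) {
      # alternate the sign of the shared factor to induce negative pairs
      flip <- seq_along(idx) %% 2 == 0
      x[, idx[flip]] <- x[, idx[flip]] - 2 * sqrt(abs(rho)) * shared
    }
  }
  x
}

draw_expr <- function(ids, n_features, n_inf, resistant, config, platform) {
  x <- block_noise(length(resistant), n_features, config$block_size,
                   config$block_rho)
  idx <- informative_indices(n_features, n_inf, config$block_size)
  if (length(idx) > 0 && any(resistant)) {
    x[resistant, idx] <- x[resistant, idx] + config$effect_shift
  }
  dimnames(x) <- list(ids, feature_ids(platform, n_features))
  x
}

draw_survival <- function(resistant, config) {
  hr <- config$hazard_ratio_pd^resistant
  lam_pfs <- config$baseline_hazard * hr
  lam_os <- config$baseline_hazard / 2 * hr
  cens_scale <- config$censor_rate / max(1 - config$censor_rate, 1e-9)
  draw_endpoint <- function(lam) {
    t_event <- rexp(length(lam), rate = lam)
    t_cens <- rexp(length(lam), rate = mean(lam) * cens_scale)
    tibble(time = ceiling(pmin(t_event, t_cens)), event = t_event <= t_cens)
  }
  pfs <- draw_endpoint(lam_pfs)
  os <- draw_endpoint(lam_os)
  tibble(pfs_time = pfs$time, pfs_event = pfs$event,
         os_time = os$time, os_event = os$event)
}

draw_stage_vars <- function(resistant) {
  n <- length(resistant)
  p <- function(base, worse) ifelse(resistant, worse, base)
  tibble(
    t_stage = ifelse(runif(n) < p(0.12, 0.30), "T3_4", "T1_2"),
    n_stage = ifelse(runif(n) < p(0.50, 0.70), "N1_3", "N0"),
    m_stage = ifelse(runif(n) < p(0.02, 0.20), "M1", "M0"),
    stage = ifelse(runif(n) < p(0.21, 0.60), "III_IV", "I_II")
  )
}

draw_regimens_pd <- function(n_pd, arm_mix) {
  p_serd <- arm_mix["SERD"] / (arm_mix["SERM"] + arm_mix["SERD"])
  if (n_pd %% 2 == 0) {
    n_ai <- n_pd / 2
  } else {
    p_ai <- arm_mix["AI"]
    n_ai <- rbinom(1, n_pd, p_ai / sum(arm_mix))
    n_ai <- min(max(n_ai, 1L), n_pd - 1L)  # keep both PD arms populated
  }
  serm_serd <- ifelse(runif(n_pd - n_ai) < p_serd, "SERD", "SERM")
  c(rep("AI", n_ai), serm_serd)
}

#' Generate a matched TR/ET cohort pair
#'
#' Draws both study arms from one seeded generator: the TR arm with
#' `n_cr + n_pd` labelled samples (PD regimens split evenly between AI and
#' SERM/SERD when `n_pd` is even) and the ET arm with a latent resistance
#' indicator at the configured prevalence driving the same planted marker
#' shifts and hazard multiplier. The global RNG state is restored on exit.
#'
#' @param config A [sim_config()].
#' @return Named list with elements `tr` and `et`, both [cohort()] objects.
#'   The ET cohort's latent indicator is attached as attribute
#'   `latent_resistant` (named logical) for use by simulations and tests.
#' @export
simulate_cohort_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  tr <- simulate_arm(config, arm = "TR")
  et <- simulate_arm(config, arm = "ET")
  list(tr = tr, et = et)
}

simulate_arm <- function(config, arm) {
  if (arm == "TR") {
    n <- config$n_cr + config$n_pd
    resistant <- c(rep(FALSE, config$n_cr), rep(TRUE, config$n_pd))
    response <- ifelse(resistant, "PD", "CR")
    regimen <- character(n)
    regimen[!resistant] <- sample(names(config$arm_mix), config$n_cr,
                                  replace = TRUE, prob = config$arm_mix)
    regimen[resistant] <- draw_regimens_pd(config$n_pd, config$arm_mix)
    ids <- sprintf("TR-%03d", seq_len(n))
  } else {
    n <- config$n_et
    resistant <- runif(n) < config$et_resistance_prevalence
    response <- rep("unknown", n)
    regimen <- sample(names(config$arm_mix), n, replace = TRUE,
                      prob = config$arm_mix)
    ids <- sprintf("ET-%03d", seq_len(n))
  }

  clinical <- bind_rows(tibble(
    sample_id = ids, cohort_arm = arm, response = response, regimen = regimen,
    age_years = pmin(pmax(round(rnorm(n, 58, 10)), 30), 90)
  ))
  clinical <- dplyr::bind_cols(clinical, draw_stage_vars(resistant),
                               draw_survival(resistant, config))

  rna <- draw_expr(ids, config$n_rna_features, config$n_informative_rna,
                   resistant, config, "RNA")
  rppa_all <- draw_expr(ids, config$n_rppa_features,
                        config$n_informative_rppa, resistant, config, "RPPA")
  rppa <- rppa_all[rppa_subset(ids, resistant, config$rppa_subset_fraction), ,
                   drop = FALSE]

  out <- cohort(clinical, rna, rppa)
  attr(out, "latent_resistant") <-
    set_names(resistant, ids)[out$clinical$sample_id]
  out
}

# stratified so the minority class keeps proportional RPPA representation;
# total size = round(fraction * n)
rppa_subset <- function(ids, resistant, fraction) {
  n_total <- round(fraction * length(ids))
  n_res <- min(round(fraction * sum(resistant)), n_total)
  pick_res <- sample(ids[resistant], n_res)
  pick_rest <- sample(ids[!resistant], n_total - n_res)
  sort(c(pick_res, pick_rest))
}
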