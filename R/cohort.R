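#' Two-arm cohort container
#'
#' A cohort bundles one clinical table with the expression matrices measured
#' on its samples: RNA-seq (z-score scale, always present) and optionally
#' RPPA (level-3 normalized protein values, typically available for a subset
#' of samples). The constructor validates the cross-references and
#' canonicalizes ordering so that cohorts written to disk and read back
#' compare equal.
#'
#' @param clinical A data frame with one row per sample and columns
#'   `sample_id`, `cohort_arm` (`"TR"` or `"ET"`), `response`
#'   (`"CR"`, `"PD"`, `"unknown"`), `regimen` (`"AI"`, `"SERM"`, `"SERD"`),
#'   `age_years`, `t_stage` (`"T1_2"`/`"T3_4"`), `n_stage` (`"N0"`/`"N1_3"`),
#'   `m_stage` (`"M0"`/`"M1"`), `stage` (`"I_II"`/`"III_IV"`),
#'   `pfs_time`, `pfs_event`, `os_time`, `os_event`. Times are in days;
#'   events are logical.
#' @param rna Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns.
#' @param rppa Optional numeric matrix with the same layout; its samples must
#'   be a subset of the RNA samples.
#'
#' @return An object of class `crossres_cohort`: a list with elements
#'   `clinical` (tibble, sorted by sample id), `rna` and `rppa` (matrices with
#'   rows aligned to the clinical table).
#' @export
#' @examples
#' pair <- simulate_cohort_pair(sim_config(seed = 1, n_et = 40,
#'                                          n_rna_features = 20,
#'                                          n_rppa_features = 8))
#' pair$tr
cohort <- function(clinical, rna, rppa = NULL) {
  clinical <- as_tibble(clinical)
  required <- c("sample_id", "cohort_arm", "response", "regimen", "age_years",
                "t_stage", "n_stage", "m_stage", "stage",
                "pfs_time", "pfs_event", "os_time", "os_event")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort("duplicate sample ids in clinical table")
  }
  arm <- unique(clinical$cohort_arm)
  if (length(arm) != 1L || !arm %in% c("TR", "ET")) {
    abort("cohort_arm must be uniform and one of 'TR', 'ET'")
  }
  if (arm == "ET" && !all(clinical$response == "unknown")) {
    abort("ET-arm samples must have response = 'unknown'")
  }
  if (arm == "TR" && any(clinical$response == "unknown")) {
    abort("TR-arm samples must have a CR/PD response")
  }
  if (any(clinical$pfs_time < 0, na.rm = TRUE) ||
      any(clinical$os_time < 0, na.rm = TRUE)) {
    abort("survival times must be nonnegative")
  }

  clinical <- arrange(clinical, .data$sample_id)
  rna <- validate_expr(rna, clinical$sample_id, "RNA", subset_ok = FALSE)
  if (!is.null(rppa)) {
    rppa <- validate_expr(rppa, clinical$sample_id, "RPPA", subset_ok = TRUE)
    if (!all(rownames(rppa) %in% rownames(rna))) {
      abort("RPPA sample set must be a subset of the RNA sample set")
    }
  }
  structure(list(clinical = clinical, rna = rna, rppa = rppa),
            class = "crossres_cohort")
}

validate_expr <- function(values, sample_ids, platform, subset_ok) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort(paste(platform, "matrix must be a numeric matrix"))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort(paste(platform, "matrix needs sample rownames and feature colnames"))
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste("duplicate sample ids in", platform, "matrix"))
  }
  if (anyDuplicated(colnames(values))) {
    abort(paste("duplicate feature ids in", platform, "matrix"))
  }
  unknown <- setdiff(rownames(values), sample_ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown sample in ", platform, " matrix: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  if (!subset_ok && !setequal(rownames(values), sample_ids)) {
    abort(paste(platform, "matrix must cover every clinical sample"))
  }
  values[order(rownames(values)), , drop = FALSE]
}

#' @export
print.crossres_cohort <- function(x, ...) {
  arm <- x$clinical$cohort_arm[1]
  cat("<crossres_cohort> arm =", arm,
      "|", nrow(x$clinical), "samples |",
      ncol(x$rna), "RNA features")
  if (!is.null(x$rppa)) {
    cat(" |", nrow(x$rppa), "RPPA samples x", ncol(x$rppa), "features")
  }
  cat("\n")
  if (arm == "TR") {
    tab <- table(x$clinical$response)
    cat("  response:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Extract an expression matrix from a cohort
#'
#' @param cohort A [cohort()] object.
#' @param platform `"RNA"` or `"RPPA"`.
#' @return Numeric matrix (samples x features), or `NULL` when the cohort
#'   carries no RPPA data.
#' @export
expr_matrix <- function(cohort, platform = c("RNA", "RPPA")) {
  platform <- arg_match(platform)
  if (platform == "RNA") cohort$rna else cohort$rppa
}

#' Per-arm treatment groups used throughout the screen
#'
#' Maps each TR-cohort sample to one of the three screening groups:
#' responders (`CR`), progressors on aromatase inhibitors (`AI_PD`), and
#' progressors on SERM or SERD (`SERM_SERD_PD`). SERM and SERD are kept
#' distinct in the clinical table but always analysed as one arm.
#'
#' @param cohort A TR-arm [cohort()].
#' @return Named character vector, names = sample ids.
#' @export
screen_groups <- function(cohort) {
  cl <- cohort$clinical
  if (cl$cohort_arm[1] != "TR") abort("screen groups are defined for the TR arm")
  grp <- ifelse(cl$response == "CR", "CR",
                ifelse(cl$regimen == "AI", "AI_PD", "SERM_SERD_PD"))
  set_names(grp, cl$sample_id)
}

CLINICAL_COLS <- c("sample_id", "cohort_arm", "response", "regimen",
                   "age_years", "t_stage", "n_stage", "m_stage", "stage",
                   "pfs_time", "pfs_event", "os_time", "os_event")

#' Read a cohort from tab-separated files
#'
#' Matrices may be stored sample-major (rows = samples) or feature-major
#' (rows = features); orientation is auto-detected by matching ids against
#' the clinical table. Any of `NA`, `NaN` or an empty cell is treated as
#' missing.
#'
#' @param clinical_path,rna_path Paths to the clinical table and RNA matrix
#'   (TSV, one header row).
#' @param rppa_path Optional path to the RPPA matrix; when omitted the
#'   downstream RPPA stages are skipped.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(clinical_path, rna_path, rppa_path = NULL) {
  for (p in c(clinical_path, rna_path, rppa_path)) {
    if (!file.exists(p)) abort(paste("missing file:", p))
  }
  clinical <- readr::read_tsv(clinical_path, col_types = readr::cols(
    sample_id = "c", cohort_arm = "c", response = "c", regimen = "c",
    age_years = "d", t_stage = "c", n_stage = "c", m_stage = "c", stage = "c",
    pfs_time = "d", pfs_event = "l", os_time = "d", os_event = "l"
  ), na = c("NA", "NaN", ""), progress = FALSE)
  rna <- read_expr_tsv(rna_path, clinical$sample_id)
  rppa <- if (!is.null(rppa_path)) read_expr_tsv(rppa_path, clinical$sample_id)
  cohort(clinical, rna, rppa)
}

read_expr_tsv <- function(path, sample_ids) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (ncol(raw) < 2) abort(paste("matrix file has no data columns:", path))
  id_col <- raw[[1]]
  sample_major <- length(intersect(id_col, sample_ids)) > 0
  feature_major <- length(intersect(names(raw)[-1], sample_ids)) > 0
  if (!sample_major && !feature_major) {
    abort(paste("zero overlapping samples between clinical table and", path))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  missing_mask <- cells %in% c("NA", "NaN", "") | is.na(cells)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- is.na(num) & !missing_mask
  if (any(bad)) {
    abort(paste0("non-numeric cell in ", path, ": '",
                 cells[which(bad)[1]], "'"))
  }
  dimnames(num) <- list(id_col, colnames(cells))
  if (!sample_major) num <- t(num)
  num
}

#' Write a cohort to a directory as TSV files
#'
#' Emits `clinical.tsv` plus one sample-major matrix file per platform
#' (`rna.tsv`, `rppa.tsv`). Sample ids are written in sorted order and
#' missing values as `NA`, so two writes of the same cohort are
#' byte-identical.
#'
#' @param cohort A [cohort()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, "clinical.tsv")
  readr::write_tsv(cohort$clinical, paths[1], na = "NA", progress = FALSE)
  paths <- c(paths, write_expr_tsv(cohort$rna, file.path(directory, "rna.tsv")))
  if (!is.null(cohort$rppa)) {
    paths <- c(paths, write_expr_tsv(cohort$rppa, file.path(directory, "rppa.tsv")))
  }
  invisible(paths)
}

write_expr_tsv <- function(values, path) {
  df <- as_tibble(values, rownames = "sample_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  path
}
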