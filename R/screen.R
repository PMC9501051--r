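#' Flag outlier features per treatment group
#'
#' A feature is flagged for a group when at least a `min_fraction` share of
#' the group's samples lie at or beyond the z-score threshold in either
#' direction (|z| >= `z_threshold`, boundary inclusive). The default
#' `min_fraction = NULL` means "at least one sample", the usual convention
#' for outlier-style screens of small groups.
#'
#' @param values Samples-by-features numeric matrix, or a [cohort()]
#'   (with `platform` selecting the matrix).
#' @param groups Named character vector mapping sample id to group; every
#'   sample in `values` must be assigned. Typically [screen_groups()].
#' @param z_threshold Absolute z-score threshold (default 2).
#' @param min_fraction Minimum flagged fraction per group; `NULL` = any one
#'   sample.
#' @param platform Used when `values` is a cohort.
#' @return Object of class `feature_flags`: per-group feature-id sets plus
#'   the screen parameters.
#' @export
flag_features <- function(values, groups, z_threshold = 2,
                          min_fraction = NULL, platform = "RNA") {
  if (inherits(values, "crossres_cohort")) {
    values <- expr_matrix(values, platform)
  }
  groups <- groups[rownames(values)]
  if (anyNA(groups)) abort("every sample must be assigned to a group")
  sets <- list()
  sizes <- integer()
  for (g in sort(unique(groups))) {
    rows <- values[groups == g, , drop = FALSE]
    if (nrow(rows) == 0) abort(paste("empty group:", g))
    hits <- colSums(abs(rows) >= z_threshold, na.rm = TRUE)
    need <- if (is.null(min_fraction)) 1L else min_fraction * nrow(rows)
    sets[[g]] <- colnames(values)[hits >= need & hits > 0]
    sizes[[g]] <- nrow(rows)
  }
  structure(list(sets = sets, z_threshold = z_threshold,
                 min_fraction = min_fraction, group_sizes = sizes),
            class = "feature_flags")
}

#' @export
print.feature_flags <- function(x, ...) {
  cat("<feature_flags> |z| >=", x$z_threshold, "\n")
  for (g in names(x$sets)) {
    cat(" ", g, ": ", length(x$sets[[g]]), " features (n=",
        x$group_sizes[[g]], ")\n", sep = "")
  }
  invisible(x)
}

#' Exact 7-region partition of three feature sets
#'
#' @param sets A [flag_features()] result, or a named list of exactly three
#'   character vectors.
#' @return Object of class `venn_partition`: disjoint `regions` (named
#'   `only_<set>`, `<set1>.<set2>`, `triple`) whose union equals the union
#'   of the inputs, plus `counts`.
#' @export
venn_partition <- function(sets) {
  if (inherits(sets, "feature_flags")) sets <- sets$sets
  if (length(sets) != 3 || is.null(names(sets))) {
    abort("venn_partition needs exactly three named sets")
  }
  nm <- names(sets)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0) member <- matrix(logical(0), 0, 3)
  key <- member %*% c(1, 2, 4)
  regions <- list()
  regions[[paste0("only_", nm[1])]] <- u[key == 1]
  regions[[paste0("only_", nm[2])]] <- u[key == 2]
  regions[[paste0("only_", nm[3])]] <- u[key == 4]
  regions[[paste(nm[1], nm[2], sep = ".")]] <- u[key == 3]
  regions[[paste(nm[1], nm[3], sep = ".")]] <- u[key == 5]
  regions[[paste(nm[2], nm[3], sep = ".")]] <- u[key == 6]
  regions[["triple"]] <- u[key == 7]
  structure(list(regions = regions, counts = lengths(regions),
                 set_names = nm),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  print(x$counts)
  invisible(x)
}

#' Cross-resistance candidate region of the Venn partition
#'
#' The candidates are the features flagged in both progressor arms —
#' the AI/SERM-SERD pair-only region together with the triple region (which
#' additionally involves CR). Equivalently, the plain intersection of the
#' two PD-arm sets.
#'
#' @param partition A [venn_partition()].
#' @param pd_sets Names of the two progressor-arm sets.
#' @return Sorted character vector of candidate feature ids.
#' @export
candidate_region <- function(partition,
                             pd_sets = c("AI_PD", "SERM_SERD_PD")) {
  stopifnot(inherits(partition, "venn_partition"))
  if (!all(pd_sets %in% partition$set_names)) {
    abort("pd_sets must name two of the partitioned sets")
  }
  nm <- partition$set_names
  pair_key <- intersect(
    grep("\\.", names(partition$regions), value = TRUE),
    names(partition$regions)[map_lgl(names(partition$regions), function(k) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      setequal(parts, pd_sets)
    })]
  )
  sort(unique(c(partition$regions[[pair_key]], partition$regions$triple)))
}
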