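# Descriptor screening heuristics and correlation pruning applied before
# subset selection.

#' Default descriptor blacklist
#'
#' Descriptors excluded a priori as unrelated to binding affinity:
#' synthesizability / feasibility-type scores. Configurable; the shipped
#' default covers the common synthetic-accessibility names.
#'
#' @return Character vector of descriptor names.
#' @export
default_descriptor_blacklist <- function() {
  c("rsynth", "SAscore", "sascore", "synth_feasibility", "QED")
}

#' Screen a descriptor matrix
#'
#' Removes, in order: (1) blacklisted descriptor names; (2) columns whose
#' fraction of zero values exceeds `zero_fraction_threshold` (default 0.95 -
#' descriptors that are 0 in most molecules cannot rank affinities);
#' (3) columns with at most `distinct_value_threshold` distinct values
#' (default 2 - near-binary descriptors). Column order of retained
#' descriptors is preserved.
#'
#' @param matrix A `descriptor_matrix` (or numeric matrix).
#' @param blacklist Names to drop a priori.
#' @param zero_fraction_threshold Exclusive zero-fraction cutoff.
#' @param distinct_value_threshold Columns with `<=` this many distinct
#'   values are dropped.
#' @return List with `matrix` (screened `descriptor_matrix`) and `report`
#'   (a `screen_report`: named exclusion reasons and thresholds).
#' @export
screen_descriptors <- function(matrix,
                               blacklist = default_descriptor_blacklist(),
                               zero_fraction_threshold = 0.95,
                               distinct_value_threshold = 2L) {
  dm <- if (inherits(matrix, "descriptor_matrix")) matrix else descriptor_matrix(matrix)
  X <- dm$values
  if (!ncol(X) || !nrow(X)) stop_gg("empty descriptor matrix")
  if (anyNA(X)) stop_gg("descriptor matrix contains missing values")
  excluded <- character(0)

  for (nm in colnames(X)) {
    if (nm %in% blacklist) {
      excluded[nm] <- "blacklist"
    } else if (mean(X[, nm] == 0) > zero_fraction_threshold) {
      excluded[nm] <- "zero_dominant"
    } else if (length(unique(X[, nm])) <= distinct_value_threshold) {
      excluded[nm] <- "near_binary"
    }
  }
  retained <- setdiff(colnames(X), names(excluded))
  if (!length(retained)) stop_gg("no descriptors survive screening")
  list(
    matrix = descriptor_matrix(X[, retained, drop = FALSE], provider = dm$provider),
    report = structure(list(
      excluded = excluded,
      retained_names = retained,
      zero_fraction_threshold = zero_fraction_threshold,
      distinct_value_threshold = as.integer(distinct_value_threshold)
    ), class = "screen_report")
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Descriptor screen: %d retained, %d excluded\n",
              length(x$retained_names), length(x$excluded)))
  if (length(x$excluded)) {
    tab <- table(x$excluded)
    for (r in names(tab)) cat(sprintf("  %-13s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Prune highly correlated descriptors
#'
#' Greedy grouping by absolute Pearson correlation: descriptors are visited
#' in a deterministic order and each still-unassigned descriptor collects
#' every later descriptor correlated with it above `threshold` into its
#' group; one representative per group is kept. The representative is the
#' member most correlated (absolutely) with the response when `y` is given,
#' otherwise the lexicographically smallest name; `representative =
#' "random"` instead samples one member under `seed`. Zero-variance columns
#' are excluded with reason `correlated-degenerate`. Group membership is
#' returned for later swap refinement by [greedgene()].
#'
#' @param matrix `descriptor_matrix` or numeric matrix (post-screening).
#' @param threshold Absolute-correlation grouping threshold (default 0.9).
#' @param y Optional response used to pick group representatives.
#' @param representative `"best"` (default) or `"random"`.
#' @param seed Seed used when `representative = "random"`.
#' @return List with `matrix` (pruned), `groups` (named list representative
#'   -> all members), and `excluded` (named reasons for dropped columns).
#' @export
prune_correlated <- function(matrix, threshold = 0.9, y = NULL,
                             representative = c("best", "random"),
                             seed = 1L) {
  representative <- match.arg(representative)
  dm <- if (inherits(matrix, "descriptor_matrix")) matrix else descriptor_matrix(matrix)
  X <- dm$values
  sds <- apply(X, 2, stats::sd)
  excluded <- character(0)
  degenerate <- colnames(X)[sds == 0]
  for (nm in degenerate) excluded[nm] <- "correlated-degenerate"
  live <- setdiff(colnames(X), degenerate)
  if (!length(live)) stop_gg("no descriptors survive correlation pruning")

  C <- abs(stats::cor(X[, live, drop = FALSE]))
  assigned <- character(0)
  groups <- list()
  for (nm in live) {
    if (nm %in% assigned) next
    members <- setdiff(live[C[nm, ] > threshold], assigned)
    members <- union(nm, members)
    assigned <- c(assigned, members)
    rep_nm <- if (length(members) == 1L) {
      members
    } else if (representative == "random") {
      with_seed(seed + length(groups), sample(members, 1L))
    } else if (!is.null(y)) {
      ry <- abs(stats::cor(X[, members, drop = FALSE], y))
      members[order(-ry, members)][1L]
    } else {
      sort(members)[1L]
    }
    groups[[rep_nm]] <- sort(members)
    for (m in setdiff(members, rep_nm)) excluded[m] <- "correlated"
  }
  keep <- colnames(X)[colnames(X) %in% names(groups)]
  list(
    matrix = descriptor_matrix(X[, keep, drop = FALSE], provider = dm$provider),
    groups = groups,
    excluded = excluded
  )
}
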