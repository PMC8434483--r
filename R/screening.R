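# Virtual screening: applicability-domain filter chain, pKi prediction over
# a library, Tanimoto-based decoy selection, and enrichment metrics.

#' Filter a screening library for drug-likeness and applicability domain
#'
#' Applies, per compound: Lipinski's Rule of Five (MW <= 500, logP <= 5,
#' H-bond donors <= 5, acceptors <= 10; strict by default, i.e. zero
#' violations, with `ro5_allowed_violations = 1` for the common relaxed
#' form), presence of a basic nitrogen, at most two positively chargeable
#' groups, no unspecified stereocentres, an organic-element whitelist
#' \{H,C,N,O,S,P,F,Cl,Br,I\} (inorganics are rejected), and an amide-bond
#' count threshold (default more than 4 amides = peptidomimetic). Rejection
#' reasons are cumulative; input order is preserved; unparsable structures
#' are rejected as `parse_error`.
#'
#' @param library data.frame with `id` and `smiles`, or named character
#'   vector of SMILES.
#' @param ro5_allowed_violations Number of Lipinski violations tolerated
#'   (default 0).
#' @param max_positive_groups Maximum count of basic/charged nitrogen groups.
#' @param max_amide_bonds Amide-bond count above which a compound is flagged
#'   peptidomimetic.
#' @param require_basic_n Require at least one basic nitrogen (ring
#'   placement not required at this stage).
#' @param exclude_unspecified_stereo Reject racemic/unspecified
#'   stereocentres (they fall outside the model's applicability domain).
#' @return List with `kept` (data.frame `id`, `smiles`) and `rejected`
#'   (`id`, `smiles`, `reasons`).
#' @export
filter_library <- function(library,
                           ro5_allowed_violations = 0L,
                           max_positive_groups = 2L,
                           max_amide_bonds = 4L,
                           require_basic_n = TRUE,
                           exclude_unspecified_stereo = TRUE) {
  lib <- as_library(library)
  props <- library_ro5_props(lib$smiles, lib$id)
  kept <- list(); rejected <- list()
  for (k in seq_len(nrow(lib))) {
    id <- lib$id[[k]]; smi <- lib$smiles[[k]]
    g <- parse_smiles(smi, id)
    if (is.null(g) || length(g$heavy) < 1L || is.na(props$MW[k])) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        id = id, smiles = smi, reasons = "parse_error", stringsAsFactors = FALSE)
      next
    }
    reasons <- character(0)
    viol <- c(
      ro5_mw = props$MW[k] > 500,
      ro5_logp = props$logP[k] > 5,
      ro5_hbd = props$HBD[k] > 5,
      ro5_hba = props$HBA[k] > 10
    )
    if (sum(viol) > ro5_allowed_violations) reasons <- c(reasons, names(viol)[viol])
    if (require_basic_n && !any(is_basic_n(g))) reasons <- c(reasons, "no_basic_N")
    if (count_positive_groups(g) > max_positive_groups) reasons <- c(reasons, "positive_groups")
    if (exclude_unspecified_stereo && has_unspecified_stereo(g)) {
      reasons <- c(reasons, "unspecified_stereo")
    }
    if (!organic_elements_only(g)) reasons <- c(reasons, "element")
    if (count_amide_bonds(g) > max_amide_bonds) reasons <- c(reasons, "peptidomimetic")
    if (length(reasons)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        id = id, smiles = smi, reasons = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    } else {
      kept[[length(kept) + 1L]] <- data.frame(id = id, smiles = smi,
                                              stringsAsFactors = FALSE)
    }
  }
  list(
    kept = if (length(kept)) do.call(rbind, kept) else
      data.frame(id = character(), smiles = character()),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(id = character(), smiles = character(), reasons = character())
  )
}

as_library <- function(library) {
  if (is.data.frame(library)) {
    stopifnot(all(c("id", "smiles") %in% names(library)))
    return(library[, c("id", "smiles")])
  }
  data.frame(
    id = names(library) %||% sprintf("lib%05d", seq_along(library)),
    smiles = as.character(library), stringsAsFactors = FALSE
  )
}

# RO5 properties per compound through Open Babel; NA rows mark parse failures
library_ro5_props <- function(smiles, ids) {
  out <- data.frame(MW = rep(NA_real_, length(smiles)), logP = NA_real_,
                    HBD = NA_real_, HBA = NA_real_)
  for (k in seq_along(smiles)) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[[k]])),
                    error = function(e) NULL)
    if (is.null(sdf)) next
    p <- tryCatch(suppressWarnings(ChemmineR::propOB(sdf)), error = function(e) NULL)
    if (is.null(p) || !nrow(p)) next
    out$MW[k] <- p$MW[1]
    out$logP[k] <- p$logP[1]
    out$HBD[k] <- p$HBD[1]
    out$HBA[k] <- p$HBA1[1]
  }
  out
}

#' Predict pKi over a screening library and apply the activity cutoff
#'
#' @param model A `qsar_model` (e.g. [published_model()] or a [fit_mlr()]
#'   fit).
#' @param matrix Descriptor matrix containing every descriptor the model
#'   names (rows = library compounds).
#' @param cutoff Predicted-pKi activity cutoff; the comparison is inclusive
#'   (`>=`), so a prediction exactly at the cutoff passes.
#' @return data.frame of hits sorted by predicted pKi descending: `id`,
#'   `predicted_pki`, `passed` (cutoff flag).
#' @export
predict_library <- function(model, matrix, cutoff = 5.5) {
  X <- as_descriptor_values(matrix)
  pred <- predict(model, X)
  out <- data.frame(
    id = rownames(X) %||% sprintf("lib%05d", seq_along(pred)),
    predicted_pki = as.numeric(pred),
    passed = as.numeric(pred) >= cutoff,
    stringsAsFactors = FALSE
  )
  out[order(-out$predicted_pki, out$id), , drop = FALSE]
}

#' Maximum Tanimoto coefficient of candidates against an actives set
#'
#' FP2 path-based fingerprints (1024 bits) are computed for both sets and
#' each candidate is assigned its maximum Tanimoto similarity to any
#' active. The fingerprint choice is configurable through `fp_type`
#' (any type Open Babel supports); decoy selection can also consume
#' precomputed `max_tc` values to decouple from the fingerprint entirely.
#'
#' @param candidates data.frame with `id`, `smiles` (or named SMILES
#'   vector).
#' @param actives data.frame with `id`, `smiles` (or named SMILES vector).
#' @param fp_type Open Babel fingerprint type (default `"FP2"`).
#' @return data.frame `id`, `smiles`, `max_tc`.
#' @export
max_tanimoto <- function(candidates, actives, fp_type = "FP2") {
  cand <- as_library(candidates)
  act <- as_library(actives)
  A <- fp_bit_matrix(act$smiles, act$id, fp_type)
  if (!nrow(A)) stop_gg("no active structure could be fingerprinted")
  C <- fp_bit_matrix(cand$smiles, cand$id, fp_type)
  failed <- setdiff(cand$id, rownames(C))
  if (length(failed)) {
    warning("dropping unfingerprintable candidate(s): ", paste(failed, collapse = ", "))
    cand <- cand[cand$id %in% rownames(C), , drop = FALSE]
  }
  inter <- C %*% t(A)                       # |c & a|
  tot_c <- rowSums(C); tot_a <- rowSums(A)
  uni <- outer(tot_c, tot_a, `+`) - inter   # |c | a|
  tc <- inter / pmax(uni, 1)
  data.frame(id = cand$id, smiles = cand$smiles,
             max_tc = apply(tc, 1L, max), stringsAsFactors = FALSE)
}

# logical fingerprint matrix, one row per parsable molecule; molecules are
# converted one at a time because a batch conversion stops at the first
# unparsable SMILES
fp_bit_matrix <- function(smiles, ids, fp_type) {
  rows <- list()
  for (k in seq_along(smiles)) {
    fp <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(
        stats::setNames(smiles[[k]], ids[[k]])))
      suppressWarnings(ChemmineR::fingerprintOB(sdf, fp_type))@fpma[1L, ]
    }, error = function(e) NULL)
    if (!is.null(fp)) rows[[ids[[k]]]] <- fp > 0
  }
  if (!length(rows)) return(matrix(logical(0), 0, 0))
  do.call(rbind, rows)
}

#' Select decoys as the most dissimilar fraction of candidates
#'
#' Candidates are sorted by ascending maximum Tanimoto coefficient to the
#' actives and the lowest `floor(fraction * n)` are kept as decoys (ties at
#' the boundary broken by id).
#'
#' @param candidates data.frame with `id` and `max_tc` columns (e.g. from
#'   [max_tanimoto()]).
#' @param fraction Fraction of candidates to keep (default 0.25).
#' @return The selected rows of `candidates`, sorted by `max_tc` then id.
#' @export
select_decoys <- function(candidates, fraction = 0.25) {
  stopifnot(is.data.frame(candidates), all(c("id", "max_tc") %in% names(candidates)))
  if (!nrow(candidates)) stop_gg("empty candidate list")
  if (fraction <= 0 || fraction > 1) stop_gg("fraction must be in (0, 1]")
  n_keep <- floor(fraction * nrow(candidates))
  ord <- order(candidates$max_tc, candidates$id)
  candidates[ord[seq_len(n_keep)], , drop = FALSE]
}

#' Assemble a screening evaluation set from actives and decoys
#'
#' Binds actives (label 1) and decoys (label 0) into one table, the form of
#' evaluation database used for enrichment statistics: e.g. 191 actives
#' with 12,148 decoys give a 12,339-entry set.
#'
#' @param actives data.frame with `id` (and optionally `smiles`).
#' @param decoys Likewise.
#' @return data.frame `id`, `smiles`, `active` (0/1); an attribute
#'   `counts` records A, D and the actives:decoys ratio.
#' @export
assemble_screening_set <- function(actives, decoys) {
  a <- as_screen_rows(actives, 1L)
  d <- as_screen_rows(decoys, 0L)
  if (length(intersect(a$id, d$id))) stop_gg("actives and decoys share ids")
  out <- rbind(a, d)
  attr(out, "counts") <- list(A = nrow(a), D = nrow(out),
                              ratio = nrow(d) / max(1L, nrow(a)))
  out
}

as_screen_rows <- function(x, label) {
  x <- if (is.data.frame(x)) x else data.frame(id = as.character(x))
  data.frame(id = x$id, smiles = x$smiles %||% NA_character_,
             active = label, stringsAsFactors = FALSE)
}

#' Confusion counts and enrichment metrics for a screen
#'
#' Computes TP/TN/FP/FN against the actives, then sensitivity
#' TP/(TP + FN), specificity TN/(TN + FP), and enrichment factor
#' EF = (TP/Ht)/(A/D), where Ht is the number of selected hits, A the
#' number of actives and D the database size. With `top_fraction < 1` the
#' hit list is truncated to its top fraction before counting (EF for the
#' top 1% of a ranked list is the common screening summary).
#'
#' @param predicted_active_ids Character vector of ids called active,
#'   ranked best-first when `top_fraction < 1`.
#' @param actives_ids Ids of the true actives (must be a subset of
#'   `database_ids`).
#' @param database_ids All ids in the screened database.
#' @param top_fraction Fraction of the ranked hit list to evaluate.
#' @return An `enrichment_report`: counts TP, TN, FP, FN, Ht, A, D;
#'   `sensitivity` and `specificity` as fractions in \[0, 1\]; `ef`; and
#'   `top_fraction`. When Ht = 0 the EF is `NA` with an explanatory
#'   `ef_note`.
#' @examples
#' evaluate_enrichment(c("a1", "d1"), c("a1", "a2"), c("a1", "a2", "d1", "d2"))
#' @export
evaluate_enrichment <- function(predicted_active_ids, actives_ids,
                                database_ids, top_fraction = 1.0) {
  predicted_active_ids <- as.character(predicted_active_ids)
  actives_ids <- as.character(actives_ids)
  database_ids <- as.character(database_ids)
  if (anyDuplicated(database_ids)) stop_gg("database ids must be unique")
  if (!all(actives_ids %in% database_ids)) stop_gg("actives must be a subset of the database")
  if (!all(predicted_active_ids %in% database_ids)) {
    stop_gg("predictions must be a subset of the database")
  }
  if (top_fraction <= 0 || top_fraction > 1) stop_gg("top_fraction must be in (0, 1]")
  hits <- if (top_fraction < 1) {
    utils::head(predicted_active_ids, max(1L, floor(top_fraction * length(predicted_active_ids))))
  } else {
    predicted_active_ids
  }
  D <- length(database_ids)
  A <- length(actives_ids)
  Ht <- length(hits)
  TP <- length(intersect(hits, actives_ids))
  FP <- Ht - TP
  FN <- A - TP
  TN <- D - A - FP
  ef <- if (Ht == 0) NA_real_ else (TP / Ht) / (A / D)
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN, Ht = Ht, A = A, D = D,
    sensitivity = if (A > 0) TP / (TP + FN) else NA_real_,
    specificity = if (D - A > 0) TN / (TN + FP) else NA_real_,
    ef = ef,
    ef_note = if (Ht == 0) "EF undefined: empty hit list" else NULL,
    top_fraction = top_fraction
  ), class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("Enrichment over %d compounds (%d actives), top fraction %.2g\n",
              x$D, x$A, x$top_fraction))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  (Ht = %d)\n", x$TP, x$FP, x$TN, x$FN, x$Ht))
  cat(sprintf("  sensitivity %.0f%%  specificity %.0f%%  EF %.1f\n",
              100 * x$sensitivity, 100 * x$specificity, x$ef))
  if (!is.null(x$ef_note)) cat(" ", x$ef_note, "\n")
  invisible(x)
}
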