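# Dataset curation: reading molecules and activities, the inclusion
# criteria of the S2R ligand collection, and Ki -> pKi conversion.

#' Convert a binding affinity Ki (nM) to pKi
#'
#' pKi = 9 - log10(Ki), with Ki in nanomolar (no unit autodetection).
#'
#' @param ki_nM Positive finite Ki value(s) in nM.
#' @param id Optional id(s) used in error messages.
#' @return Numeric pKi value(s).
#' @examples
#' convert_ki_to_pki(1)     # 9
#' convert_ki_to_pki(1000)  # 6
#' @export
convert_ki_to_pki <- function(ki_nM, id = NULL) {
  bad <- !is.finite(ki_nM) | ki_nM <= 0
  if (any(bad)) {
    lab <- if (!is.null(id)) paste(id[bad], collapse = ", ") else paste(ki_nM[bad], collapse = ", ")
    stop_gg("Ki must be positive and finite (nM); offending: ", lab)
  }
  9 - log10(ki_nM)
}

#' Curation criteria for the S2R ligand collection
#'
#' Defaults encode the inclusion rules of the modeled collection: molecular
#' weight below 500 g/mol, Ki below 5000 nM, a basic nitrogen embedded in or
#' attached to a ring, fully specified stereocentres, and exclusion of the
#' bridged 9-azabicyclo\[3.3.1\]nonane scaffold (matched as a substructure).
#'
#' @param max_mw Maximum molecular weight (g/mol, exclusive).
#' @param max_ki_nM Maximum Ki (nM, exclusive).
#' @param require_basic_ring_nitrogen Require a basic (sp3, non-amide,
#'   non-aromatic) nitrogen that is a ring member or attached to a ring.
#' @param exclude_unspecified_stereo Reject molecules with at least one
#'   stereocentre whose configuration the input SMILES leaves undefined.
#' @param excluded_scaffold_patterns Character vector of SMARTS patterns
#'   rejected as substructures.
#' @return A `curation_criteria` list.
#' @export
curation_criteria <- function(max_mw = 500, max_ki_nM = 5000,
                              require_basic_ring_nitrogen = TRUE,
                              exclude_unspecified_stereo = TRUE,
                              excluded_scaffold_patterns = "C1CCC2CCCC1N2") {
  if (max_mw <= 0 || max_ki_nM <= 0) stop_gg("thresholds must be strictly positive")
  structure(list(
    max_mw = max_mw, max_ki_nM = max_ki_nM,
    require_basic_ring_nitrogen = isTRUE(require_basic_ring_nitrogen),
    exclude_unspecified_stereo = isTRUE(exclude_unspecified_stereo),
    excluded_scaffold_patterns = excluded_scaffold_patterns
  ), class = "curation_criteria")
}

#' Curate a ligand table against the inclusion criteria
#'
#' Each record is parsed and checked against every criterion; records
#' failing any check are returned in `rejected` with the full set of reasons
#' from \{`parse_error`, `mw`, `ki`, `no_basic_ring_N`, `unspecified_stereo`,
#' `excluded_scaffold`\}. Unparsable structures are rejected, never an error.
#' Input order is preserved and `kept` plus `rejected` partition the input.
#'
#' @param records data.frame with columns `id`, `smiles`, `ki_nM` and
#'   optionally `source_ref`.
#' @param criteria A [curation_criteria()].
#' @return List with `kept` (data.frame `id`, `smiles` (canonical), `ki_nM`,
#'   `pki`, `source_ref`) and `rejected` (`id`, `smiles`, `reasons`).
#' @examples
#' \donttest{
#' curate(toy_molecule_set())
#' }
#' @export
curate <- function(records, criteria = curation_criteria()) {
  stopifnot(is.data.frame(records), all(c("id", "smiles", "ki_nM") %in% names(records)))
  if (anyDuplicated(records$id)) stop_gg("duplicate ids in records")
  src <- records$source_ref %||% rep("", nrow(records))

  kept <- list()
  rejected <- list()
  for (k in seq_len(nrow(records))) {
    id <- records$id[[k]]
    smi <- records$smiles[[k]]
    ki <- records$ki_nM[[k]]
    g <- parse_smiles(smi, id)
    if (is.null(g) || length(g$heavy) < 1L) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        id = id, smiles = smi, reasons = "parse_error", stringsAsFactors = FALSE)
      next
    }
    reasons <- character(0)
    if (molgraph_mw(g) >= criteria$max_mw) reasons <- c(reasons, "mw")
    if (!is.finite(ki) || ki <= 0 || ki >= criteria$max_ki_nM) reasons <- c(reasons, "ki")
    if (criteria$require_basic_ring_nitrogen && !has_basic_ring_nitrogen(g)) {
      reasons <- c(reasons, "no_basic_ring_N")
    }
    if (criteria$exclude_unspecified_stereo && has_unspecified_stereo(g)) {
      reasons <- c(reasons, "unspecified_stereo")
    }
    if (length(criteria$excluded_scaffold_patterns) &&
        matches_any_scaffold(smi, criteria$excluded_scaffold_patterns)) {
      reasons <- c(reasons, "excluded_scaffold")
    }
    if (length(reasons)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        id = id, smiles = smi, reasons = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    } else {
      kept[[length(kept) + 1L]] <- data.frame(
        id = id, smiles = canonical_smiles(smi),
        ki_nM = ki, pki = convert_ki_to_pki(ki, id), source_ref = src[[k]],
        stringsAsFactors = FALSE)
    }
  }
  list(
    kept = if (length(kept)) do.call(rbind, kept) else
      data.frame(id = character(), smiles = character(), ki_nM = numeric(),
                 pki = numeric(), source_ref = character()),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(id = character(), smiles = character(), reasons = character())
  )
}

canonical_smiles <- function(smiles) {
  out <- tryCatch(
    sub("[[:space:]].*$", "", trimws(suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))))),
    error = function(e) NA_character_
  )
  if (is.na(out) || !nzchar(out)) smiles else out
}

matches_any_scaffold <- function(smiles, patterns) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(FALSE)
  for (p in patterns) {
    hit <- tryCatch(
      suppressWarnings(ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = FALSE)),
      error = function(e) 0
    )
    if (any(hit > 0)) return(TRUE)
  }
  FALSE
}

#' Read molecules from a SMILES file
#'
#' One record per line, `smiles<TAB>id` (a single space separator is also
#' accepted). Lines without an id get a positional id.
#'
#' @param path Path to a SMILES file.
#' @return data.frame with `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    id = vapply(seq_along(parts), function(k) {
      if (length(parts[[k]]) > 1L) parts[[k]][[2L]] else sprintf("mol%04d", k)
    }, character(1)),
    smiles = vapply(parts, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

#' Read an activity table
#'
#' CSV with header `id,ki_nM[,source_ref]`.
#'
#' @param path CSV path.
#' @return data.frame with `id`, `ki_nM`, `source_ref`.
#' @export
read_activities <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "ki_nM") %in% names(x))) stop_gg("activity CSV needs columns id, ki_nM")
  if (is.null(x$source_ref)) x$source_ref <- ""
  x
}

#' Per-publication compound counts of the curated S2R ligand collection
#'
#' The compiled summary of the 16 literature sources of the modeled Sigma-2
#' ligand set: source index, reported pKi range, and number of compounds
#' contributed. The counts sum to the 159 curated structures.
#'
#' @return data.frame with `source_id`, `pki_min`, `pki_max`, `n_compounds`.
#' @export
sigma2_reference_counts <- function() {
  data.frame(
    source_id = 1:16,
    pki_min = c(5.48, 6.14, 6.39, 6.29, 6.18, 6.51, 7.54, 7.29, 7.52, 5.99,
                6.28, 6.62, 6.17, 7.63, 7.17, 5.33),
    pki_max = c(7.71, 8.09, 6.95, 7.59, 8.00, 8.79, 10.40, 8.58, 9.24, 8.82,
                7.64, 7.75, 8.08, 9.31, 8.52, 7.25),
    n_compounds = c(9L, 8L, 4L, 9L, 6L, 14L, 9L, 8L, 4L, 22L, 16L, 15L, 8L,
                    7L, 10L, 10L)
  )
}

#' Write curated records and rejection log to CSV
#'
#' @param curated Output of [curate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kept <- file.path(dir, "curated.csv")
  rej <- file.path(dir, "rejected.csv")
  utils::write.csv(curated$kept, kept, row.names = FALSE)
  utils::write.csv(curated$rejected, rej, row.names = FALSE)
  invisible(c(kept, rej))
}
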