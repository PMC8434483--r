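# 2D descriptor computation. The five descriptors of the published model are
# provided as documented open-toolkit analogs computed from the hydrogen-
# explicit molecular graph:
#
#   balabanJ   - Balaban's distance connectivity index J on the heavy-atom
#                graph (largest component when disconnected)
#   b_max1len  - number of bonds in the longest chain of acyclic single
#                bonds between heavy atoms
#   Q_VSA_PNEG - approximate van der Waals surface area (A^2) of atoms whose
#                Gasteiger partial charge (neutral form) is below -0.2
#   vsa_acc    - approximate vdW surface area of pure hydrogen-bond
#                acceptors (N/O bearing no hydrogen, excluding amide and
#                planar aniline-type nitrogen)
#   SlogP_VSA1 - approximate vdW surface area of atoms whose atomic logP
#                contribution falls in [-0.4, -0.2)
#
# Surface areas use the Labute-style sphere-cap approximation with Bondi vdW
# radii and ideal bond lengths from covalent radii. Atomic logP uses a
# reduced typing (SYBYL type + hydrogen count + heteroatom context) with
# Wildman-Crippen-like contribution values; numerical parity with MOE (or
# any other provider) is explicitly not promised, which is why every matrix
# carries a provider label and fitted models only predict against matrices
# from the same provider.

BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
                 S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
BOND_SHORTEN <- c(`1` = 0, am = 0, ar = 0.07, `2` = 0.14, `3` = 0.24)

#' Construct a descriptor matrix
#'
#' @param values Numeric matrix, rows = molecules (rownames = ids), columns =
#'   named descriptors.
#' @param provider Label of the descriptor provider; models fitted on one
#'   provider's values should not score another's.
#' @return A `descriptor_matrix` object.
#' @export
descriptor_matrix <- function(values, provider = "user") {
  if (!is.matrix(values) || !is.numeric(values)) stop_gg("values must be a numeric matrix")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_gg("descriptor names must be unique and non-null")
  }
  if (is.null(rownames(values))) rownames(values) <- sprintf("mol%04d", seq_len(nrow(values)))
  structure(list(values = values, provider = provider), class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("Descriptor matrix: %d molecules x %d descriptors (provider: %s)\n",
              nrow(x$values), ncol(x$values), x$provider))
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' @export
as.matrix.descriptor_matrix <- function(x, ...) x$values

#' Compute 2D descriptor analogs for curated molecules
#'
#' Computes a descriptor matrix containing the five descriptors of the
#' published model (see the package vignette for each analog's exact
#' definition) plus simple graph counts (atom/bond counts, single-bond and
#' rotatable-bond counts, ring count, connectivity indices, hydrogen-bond
#' donor/acceptor counts, molecular weight). Descriptors undefined for a
#' molecule (e.g. Balaban J of a single-atom graph) are set to 0 with a
#' warning rather than failing.
#'
#' @param molecules A curated data.frame with `id` and `smiles` columns (as
#'   returned by [curate()]), or a character vector of SMILES (optionally
#'   named by id).
#' @param names Optional subset of descriptor names to retain.
#' @return A `descriptor_matrix` with provider `"chemminer-analogs"`.
#' @examples
#' \donttest{
#' compute_descriptors(c(ethane = "CC", benzene = "c1ccccc1"))
#' }
#' @export
compute_descriptors <- function(molecules, names = NULL) {
  if (is.data.frame(molecules)) {
    smiles <- molecules$smiles
    ids <- molecules$id
  } else {
    smiles <- as.character(molecules)
    ids <- base::names(molecules) %||% sprintf("mol%04d", seq_along(smiles))
  }
  rows <- lapply(seq_along(smiles), function(k) {
    g <- parse_smiles(smiles[[k]], ids[[k]])
    if (is.null(g)) stop_gg("unparsable SMILES for id ", ids[[k]])
    molecule_descriptors(g)
  })
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  if (!is.null(names)) {
    missing <- setdiff(names, colnames(values))
    if (length(missing)) stop_gg("unknown descriptor(s): ", paste(missing, collapse = ", "))
    values <- values[, names, drop = FALSE]
  }
  descriptor_matrix(values, provider = "chemminer-analogs")
}

molecule_descriptors <- function(g) {
  vsa <- atom_vsa(g)
  logp <- atom_logp(g)
  acc <- is_pure_acceptor(g)
  heavy <- g$heavy
  hb <- heavy_bonds(g)
  c(
    balabanJ = balaban_j(g),
    b_max1len = b_max1len(g),
    Q_VSA_PNEG = sum(vsa[g$charge < -0.2]),
    vsa_acc = sum(vsa[acc]),
    SlogP_VSA1 = sum(vsa[logp >= -0.4 & logp < -0.2]),
    SlogP_VSA_pos = sum(vsa[logp >= 0.2]),
    Q_VSA_POS = sum(vsa[g$charge > 0.2]),
    a_count = length(heavy),
    b_count = nrow(hb),
    b_single = sum(hb$order %in% c("1", "am")),
    b_rot = rotatable_bonds(g),
    n_rings = nrow(hb) - length(heavy) + n_components(g),
    chi0 = chi0(g),
    chi1 = chi1(g),
    hbd = sum(g$elem %in% c("N", "O") & g$n_h > 0),
    hba = sum(acc),
    mw = molgraph_mw(g)
  )
}

heavy_bonds <- function(g) {
  keep <- g$elem[g$bonds$i] != "H" & g$elem[g$bonds$j] != "H"
  g$bonds[keep, , drop = FALSE]
}

# heavy-atom adjacency restricted to a bond subset
heavy_adj <- function(g, bonds) {
  adj <- vector("list", length(g$elem))
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  adj
}

n_components <- function(g) {
  heavy <- g$heavy
  if (!length(heavy)) return(0L)
  adj <- heavy_adj(g, heavy_bonds(g))
  seen <- logical(length(g$elem))
  ncomp <- 0L
  for (s in heavy) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  ncomp
}

# BFS distances from one heavy atom over a heavy adjacency
bfs_dist <- function(adj, n_atoms, from) {
  d <- rep(NA_integer_, n_atoms)
  d[from] <- 0L
  queue <- from
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
  }
  d
}

# Balaban's distance connectivity index J = B/(C+1) * sum over edges of
# (s_i s_j)^(-1/2), s_i the distance-matrix row sum; computed on the largest
# heavy-atom component; 0 (with a warning) when no heavy bond exists
balaban_j <- function(g) {
  hb <- heavy_bonds(g)
  if (!nrow(hb) || length(g$heavy) < 2L) {
    warning("Balaban J undefined (no heavy-atom bond); returning 0")
    return(0)
  }
  adj <- heavy_adj(g, hb)
  comp_sizes <- integer(0)
  if (n_components(g) > 1L) {
    # restrict to largest component
    seen <- logical(length(g$elem))
    best <- integer(0)
    for (s in g$heavy) {
      if (seen[s]) next
      queue <- s; seen[s] <- TRUE; head <- 1L
      while (head <= length(queue)) {
        v <- queue[head]; head <- head + 1L
        for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
      if (length(queue) > length(best)) best <- queue
    }
    keep <- hb$i %in% best & hb$j %in% best
    hb <- hb[keep, , drop = FALSE]
    atoms <- best
  } else {
    atoms <- g$heavy
  }
  if (!nrow(hb)) {
    warning("Balaban J undefined on largest component; returning 0")
    return(0)
  }
  s <- rep(NA_real_, length(g$elem))
  for (a in atoms) s[a] <- sum(bfs_dist(adj, length(g$elem), a)[atoms], na.rm = TRUE)
  B <- nrow(hb)
  C <- B - length(atoms) + 1L
  B / (C + 1) * sum(1 / sqrt(s[hb$i] * s[hb$j]))
}

# longest chain of acyclic single bonds between heavy atoms, in bonds.
# The restricted subgraph is a forest, so the longest path in each tree is
# found by a double BFS sweep.
b_max1len <- function(g) {
  hb <- heavy_bonds(g)
  keep <- hb$order %in% c("1", "am") & !g$ring_bond[match(
    paste(hb$i, hb$j), paste(g$bonds$i, g$bonds$j))]
  hb <- hb[keep, , drop = FALSE]
  if (!nrow(hb)) return(0)
  adj <- heavy_adj(g, hb)
  atoms <- unique(c(hb$i, hb$j))
  seen <- logical(length(g$elem))
  best <- 0L
  for (s in atoms) {
    if (seen[s]) next
    d1 <- bfs_dist(adj, length(g$elem), s)
    comp <- which(!is.na(d1))
    seen[comp] <- TRUE
    far <- comp[which.max(d1[comp])]
    d2 <- bfs_dist(adj, length(g$elem), far)
    best <- max(best, max(d2, na.rm = TRUE))
  }
  as.numeric(best)
}

rotatable_bonds <- function(g) {
  hb <- heavy_bonds(g)
  keep <- hb$order == "1" & !g$ring_bond[match(
    paste(hb$i, hb$j), paste(g$bonds$i, g$bonds$j))]
  hb <- hb[keep, , drop = FALSE]
  if (!nrow(hb)) return(0)
  deg <- vapply(seq_along(g$elem), function(i) heavy_degree(g, i), integer(1))
  sum(deg[hb$i] > 1L & deg[hb$j] > 1L)
}

chi0 <- function(g) {
  deg <- vapply(g$heavy, function(i) heavy_degree(g, i), integer(1))
  sum(1 / sqrt(deg[deg > 0]))
}

chi1 <- function(g) {
  hb <- heavy_bonds(g)
  if (!nrow(hb)) return(0)
  deg <- vapply(seq_along(g$elem), function(i) heavy_degree(g, i), integer(1))
  sum(1 / sqrt(deg[hb$i] * deg[hb$j]))
}

# Labute-style approximate per-atom vdW surface area (A^2): each atom's
# sphere area minus the spherical caps buried by its bonded neighbours,
# with ideal bond lengths from covalent radii shortened by bond order
atom_vsa <- function(g) {
  R <- BONDI_RADII[g$elem]
  R[is.na(R)] <- 1.70
  rc <- COVALENT_RADII[g$elem]
  rc[is.na(rc)] <- 0.77
  area <- 4 * pi * R^2
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]
    d <- rc[i] + rc[j] - (BOND_SHORTEN[g$bonds$order[r]] %||% 0)
    if (is.na(d)) d <- rc[i] + rc[j]
    d <- min(max(d, abs(R[i] - R[j]) + 0.01), R[i] + R[j] - 0.01)
    hi <- R[i] - (d^2 + R[i]^2 - R[j]^2) / (2 * d)
    hj <- R[j] - (d^2 + R[j]^2 - R[i]^2) / (2 * d)
    area[i] <- area[i] - 2 * pi * R[i] * max(0, min(hi, 2 * R[i]))
    area[j] <- area[j] - 2 * pi * R[j] * max(0, min(hj, 2 * R[j]))
  }
  pmax(area, 0)
}

# pure hydrogen-bond acceptor: N or O carrying no hydrogen, excluding amide
# and planar (aniline/pyrrole-type) nitrogen
is_pure_acceptor <- function(g) {
  ok_n <- g$elem == "N" & g$n_h == 0L & g$sybyl %in% c("N.3", "N.ar", "N.2", "N.1")
  ok_o <- g$elem == "O" & g$n_h == 0L
  ok_n | ok_o
}

# reduced atomic logP contribution table keyed on SYBYL type + context
atom_logp <- function(g) {
  out <- numeric(length(g$elem))
  hetero <- g$elem %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I")
  for (i in seq_along(g$elem)) {
    el <- g$elem[i]; ty <- g$sybyl[i]
    nbr <- g$adj[[i]]
    het_nbr <- any(hetero[nbr])
    out[i] <- switch(el,
      C = if (ty == "C.ar") {
            if (het_nbr) 0.1129 else 0.1581
          } else if (ty %in% c("C.2", "C.1")) {
            if (any(g$elem[nbr] == "O" & g$sybyl[nbr] == "O.2")) -0.2051 else 0.0017
          } else {
            if (het_nbr) -0.2035 else 0.1441
          },
      N = switch(ty,
        N.am = -0.5188,
        N.ar = -0.3239,
        N.4  = -4.0,
        N.pl3 = -1.0190,
        # aliphatic amines by substitution
        if (g$n_h[i] >= 2) -1.0190 else if (g$n_h[i] == 1) -0.7096 else -0.3187),
      O = if (ty == "O.2") -0.1188 else if (g$n_h[i] > 0) -0.2893 else -0.2057,
      S = 0.6482,
      P = 0.8612,
      F = 0.4202,
      Cl = 0.6895,
      Br = 0.8456,
      I = 0.8857,
      H = {
        ha <- nbr[g$elem[nbr] != "H"]
        if (length(ha) && g$elem[ha[1]] %in% c("N", "O")) -0.3260 else 0.1230
      },
      0
    )
  }
  out
}
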