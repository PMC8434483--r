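# Molecular graph layer: SMILES -> hydrogen-explicit MOL2 (via Open Babel
# through ChemmineOB) -> a light internal graph with SYBYL atom types,
# Gasteiger partial charges, ring perception and simple stereo/basic-N
# perception. Everything downstream (curation flags, 2D descriptors) works
# on this representation.

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                 P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
                 B = 10.81, Si = 28.085)

# parse one SMILES into a molgraph; returns NULL on parse failure
parse_smiles <- function(smiles, id = "mol") {
  mol2 <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "MOL2", paste0(smiles, " ", id, "\n"),
      options = data.frame(names = "h", args = "")
    )),
    error = function(e) ""
  )
  g <- parse_mol2(mol2)
  if (is.null(g)) return(NULL)
  g$id <- id
  g$smiles <- smiles
  g
}

# parse the first molecule of a MOL2 text block
parse_mol2 <- function(txt) {
  if (!nzchar(txt) || !grepl("@<TRIPOS>ATOM", txt, fixed = TRUE)) return(NULL)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
  b0 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
  end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  a1 <- min(end[end > a0]) - 1L
  b1 <- min(end[end > b0]) - 1L
  atom_lines <- lines[seq(a0 + 1L, a1)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(af, `[[`, "", 6L)
  charge <- vapply(af, function(f) as.numeric(f[[9L]]), numeric(1))
  elem <- sub("\\..*$", "", sybyl)

  bonds <- NULL
  if (!is.na(b0) && b0 + 1L <= b1) {
    bond_lines <- lines[seq(b0 + 1L, b1)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bonds <- data.frame(
        i = vapply(bf, function(f) as.integer(f[[2L]]), integer(1)),
        j = vapply(bf, function(f) as.integer(f[[3L]]), integer(1)),
        order = vapply(bf, `[[`, "", 4L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  }

  n <- length(elem)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  n_h <- vapply(seq_len(n), function(i) sum(elem[adj[[i]]] == "H"), integer(1))

  g <- list(elem = elem, sybyl = sybyl, charge = charge,
            bonds = bonds, adj = adj, n_h = n_h,
            heavy = which(elem != "H"))
  g$ring_bond <- ring_bonds(g)
  g$in_ring <- ring_atoms(g)
  g
}

# a bond is a ring bond iff removing it leaves its endpoints connected
# (i.e. it is not a bridge); BFS over adjacency lists carrying bond ids
ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  out <- logical(nb)
  if (!nb) return(out)
  # adjacency as (neighbour, bond id) pairs
  nbr <- vector("list", length(g$elem))
  for (r in seq_len(nb)) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]
    nbr[[i]] <- rbind(nbr[[i]], c(j, r))
    nbr[[j]] <- rbind(nbr[[j]], c(i, r))
  }
  for (r in seq_len(nb)) {
    out[r] <- connected_without(nbr, length(g$elem), g$bonds$i[r], g$bonds$j[r], r)
  }
  out
}

connected_without <- function(nbr, n_atoms, from, to, skip_bond) {
  seen <- logical(n_atoms)
  queue <- from
  seen[from] <- TRUE
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    edges <- nbr[[v]]
    if (is.null(edges)) next
    for (e in seq_len(nrow(edges))) {
      if (edges[e, 2L] == skip_bond) next
      w <- edges[e, 1L]
      if (!seen[w]) {
        if (w == to) return(TRUE)
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

ring_atoms <- function(g) {
  out <- logical(length(g$elem))
  rb <- which(g$ring_bond)
  out[unique(c(g$bonds$i[rb], g$bonds$j[rb]))] <- TRUE
  out
}

molgraph_mw <- function(g) {
  m <- ATOMIC_MASS[g$elem]
  m[is.na(m)] <- 0
  sum(m)
}

heavy_degree <- function(g, i) sum(g$elem[g$adj[[i]]] != "H")

# basic nitrogen usable as the protonation site of an S2R ligand: sp3 (or
# quaternary) non-amide non-aromatic N; the ring variant additionally asks
# that it sits in, or is directly attached to, a ring
is_basic_n <- function(g) {
  g$elem == "N" & g$sybyl %in% c("N.3", "N.4")
}

has_basic_ring_nitrogen <- function(g) {
  cand <- which(is_basic_n(g))
  for (i in cand) {
    if (g$in_ring[i]) return(TRUE)
    if (any(g$in_ring[g$adj[[i]]])) return(TRUE)
  }
  FALSE
}

# Morgan-style canonical ranks over heavy atoms (invariants: element, heavy
# degree, attached H count, ring membership), refined to a fixed point
morgan_ranks <- function(g) {
  heavy <- g$heavy
  idx <- match(seq_along(g$elem), heavy)  # atom -> heavy position
  inv <- paste(g$elem[heavy], vapply(heavy, function(i) heavy_degree(g, i), integer(1)),
               g$n_h[heavy], as.integer(g$in_ring[heavy]))
  rank <- match(inv, sort(unique(inv)))
  repeat {
    code <- vapply(seq_along(heavy), function(k) {
      nbr <- g$adj[[heavy[k]]]
      nbr <- nbr[g$elem[nbr] != "H"]
      paste(rank[k], paste(sort(rank[idx[nbr]]), collapse = ","))
    }, character(1))
    new_rank <- match(code, sort(unique(code)))
    if (length(unique(new_rank)) == length(unique(rank))) break
    rank <- new_rank
  }
  stats::setNames(rank, heavy)
}

# heuristic potential-stereocentre detector: a carbon with four substituents
# (at most one hydrogen) whose branches all receive distinct Morgan ranks.
# Global Morgan ranks resolve local and para-type symmetry; genuinely
# rank-symmetric substituents (e.g. pentan-3-ol) are correctly not flagged.
count_stereocenters <- function(g) {
  ranks <- morgan_ranks(g)
  n_sc <- 0L
  for (i in g$heavy) {
    if (g$elem[i] != "C") next
    nbr <- g$adj[[i]]
    heavy_nbr <- nbr[g$elem[nbr] != "H"]
    nh <- g$n_h[i]
    if (length(heavy_nbr) + nh != 4L || nh > 1L) next
    # sp3 only: all bonds to this atom single
    rows <- which(g$bonds$i == i | g$bonds$j == i)
    if (any(!g$bonds$order[rows] %in% c("1", "am"))) next
    codes <- as.character(ranks[as.character(heavy_nbr)])
    if (nh == 1L) codes <- c(codes, "H")
    if (anyDuplicated(codes) == 0L) n_sc <- n_sc + 1L
  }
  n_sc
}

# number of stereocentres written explicitly in the input SMILES
count_specified_stereo <- function(smiles) {
  length(gregexpr("@{1,2}", smiles)[[1]][gregexpr("@{1,2}", smiles)[[1]] > 0])
}

has_unspecified_stereo <- function(g) {
  count_stereocenters(g) > count_specified_stereo(g$smiles)
}

# count of positively-chargeable groups: basic amine nitrogens plus atoms
# carrying a formal positive charge in the input (quaternary N etc.)
count_positive_groups <- function(g) {
  sum(is_basic_n(g)) + sum(g$sybyl == "N.4" & !is_basic_n(g))
}

# amide bond count (peptidomimetic heuristic)
count_amide_bonds <- function(g) {
  sum(g$sybyl == "N.am")
}

organic_elements_only <- function(g, whitelist = c("H", "C", "N", "O", "S", "P",
                                                   "F", "Cl", "Br", "I")) {
  all(g$elem %in% whitelist)
}
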