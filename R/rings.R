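# Ring perception and ring-system extraction.
#
# Ring enumeration and per-ring aromaticity are delegated to ChemmineR's
# ring finder; the smallest set of smallest rings (SSSR) is then selected
# from the enumerated rings by greedy GF(2) cycle-space reduction (smallest
# rings first), since the enumeration also returns envelope rings.

.ring_cache_key <- function(mol) {
  paste(nrow(mol$atoms), nrow(mol$bonds),
        paste(mol$bonds$a1, mol$bonds$a2, collapse = ","))
}

# aromatic bond ids ("a-b", a < b) as perceived by OpenBabel (read from
# its MOL2 annotation, where aromatic bonds are typed "ar")
.aromatic_edges <- function(mol) {
  txt <- paste0(paste(write_sdf_text(mol), collapse = "\n"), "\n")
  m2 <- tryCatch(ChemmineOB::convertFormat("SDF", "MOL2", txt),
                 error = function(e) "")
  lines <- strsplit(m2, "\n", fixed = TRUE)[[1]]
  b0 <- grep("^@<TRIPOS>BOND", lines)
  if (!length(b0)) return(character())
  ends <- grep("^@<TRIPOS>", lines)
  end <- min(c(ends[ends > b0[1]], length(lines) + 1L)) - 1L
  rows <- trimws(lines[seq(b0[1] + 1L, end)])
  rows <- rows[nzchar(rows)]
  if (!length(rows)) return(character())
  parts <- strsplit(rows, "[ \t]+")
  ar <- vapply(parts, function(p) length(p) >= 4 && p[4] == "ar",
               logical(1))
  vapply(parts[ar], function(p) {
    a <- as.integer(p[2]); b <- as.integer(p[3])
    paste(min(a, b), max(a, b), sep = "-")
  }, character(1))
}

# all rings (index vectors, enumerated by ChemmineR) + aromatic flags
# (a ring is aromatic iff all its bonds are aromatic per OpenBabel)
.enumerate_rings <- function(mol, upper = 12) {
  if (!nrow(mol$bonds)) return(list(rings = list(), aromatic = logical()))
  circuit_rank <- nrow(mol$bonds) - nrow(mol$atoms) +
    length(.mol_components(mol))
  if (circuit_rank <= 0L) return(list(rings = list(), aromatic = logical()))
  sdf <- mols_to_sdfset(mol)[[1]]
  r <- suppressWarnings(ChemmineR::rings(sdf, upper = upper, type = "all",
                                         arom = FALSE, inner = FALSE))
  if (is.list(r) && "RINGS" %in% names(r)) r <- r$RINGS
  rings <- lapply(r, function(v) as.integer(sub("^[^_]+_", "", v)))
  # make sure the enumeration spans the cycle space; widen if it does not
  if (length(rings) < circuit_rank && upper < 40)
    return(.enumerate_rings(mol, upper = 40))
  ar_edges <- .aromatic_edges(mol)
  arom <- vapply(rings, function(ring)
    all(.ring_edges(ring) %in% ar_edges), logical(1))
  list(rings = rings, aromatic = arom)
}

# ring -> edge id vector ("a-b" with a < b)
.ring_edges <- function(ring) {
  nxt <- c(ring[-1], ring[1])
  paste(pmin(ring, nxt), pmax(ring, nxt), sep = "-")
}

#' Smallest set of smallest rings of a molecule
#'
#' @param mol a `trmol` object.
#' @return A list with `rings` (list of atom-index vectors, each a ring of
#'   the SSSR) and `aromatic` (logical flag per ring).
#' @export
mol_rings <- function(mol) {
  enum <- .enumerate_rings(mol)
  if (!length(enum$rings)) return(list(rings = list(), aromatic = logical()))
  rank_target <- nrow(mol$bonds) - nrow(mol$atoms) +
    length(.mol_components(mol))
  sizes <- lengths(enum$rings)
  keys <- vapply(enum$rings, function(r)
    paste(sort(r), collapse = ","), character(1))
  ord <- order(sizes, keys)
  edge_ids <- sort(unique(unlist(lapply(enum$rings, .ring_edges))))
  basis <- matrix(FALSE, nrow = 0, ncol = length(edge_ids))
  picked <- integer()
  for (i in ord) {
    if (length(picked) >= rank_target) break
    v <- edge_ids %in% .ring_edges(enum$rings[[i]])
    w <- v
    for (j in seq_len(nrow(basis))) {     # GF(2) reduction against basis
      p <- which(basis[j, ])[1]
      if (w[p]) w <- xor(w, basis[j, ])
    }
    if (any(w)) {
      basis <- rbind(basis, w)
      picked <- c(picked, i)
    }
  }
  list(rings = enum$rings[picked], aromatic = enum$aromatic[picked])
}

#' Count rings (SSSR cardinality)
#'
#' @param x a `trmol` or `ring_system` object.
#' @return Integer number of smallest-set-of-smallest-rings.
#' @export
count_rings <- function(x) {
  mol <- if (inherits(x, "ring_system")) x$mol else x
  nrow(mol$bonds) - nrow(mol$atoms) + length(.mol_components(mol))
}

#' Construct a ring-system record
#'
#' @param mol `trmol` holding the fused-ring assembly (every atom in a ring,
#'   except exocyclic double-bonded atoms retained by extraction).
#' @param ring_id identifier (the field's `NNN-NNN_k` style, or derived).
#' @param frequency number of approved drugs containing the ring system.
#' @return An object of class `ring_system`.
#' @export
ring_system <- function(mol, ring_id = mol$id, frequency = NA_integer_) {
  structure(list(ring_id = as.character(ring_id), mol = mol,
                 frequency = as.integer(frequency),
                 n_rings = count_rings(mol)),
            class = "ring_system")
}

#' @export
print.ring_system <- function(x, ...) {
  cat(sprintf("<ring_system %s> %d ring(s), frequency %s, %s\n",
              x$ring_id, x$n_rings,
              ifelse(is.na(x$frequency), "?", x$frequency),
              mol_formula_string(x$mol)))
  invisible(x)
}

#' Extract fused ring systems from a molecule
#'
#' Removes every acyclic atom, partitions the remaining ring atoms into
#' connected components, and returns each component as a [ring_system()].
#' Exocyclic atoms double-bonded to a ring atom (e.g. quinone oxygens) are
#' retained with their ring.  Components are returned in deterministic
#' order by canonical SMILES.
#'
#' @param mol a `trmol` object.
#' @return A list of `ring_system` objects (empty for acyclic molecules).
#' @export
extract_ring_systems <- function(mol) {
  enum <- .enumerate_rings(mol)
  if (!length(enum$rings)) return(list())
  ring_atoms <- sort(unique(unlist(enum$rings)))
  ring_edges <- unique(unlist(lapply(enum$rings, .ring_edges)))
  bond_id <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                   pmax(mol$bonds$a1, mol$bonds$a2), sep = "-")
  is_ring_bond <- bond_id %in% ring_edges
  in_ring <- function(a) a %in% ring_atoms
  exo <- integer()
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] < 2L || is_ring_bond[k]) next
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (in_ring(a) && !in_ring(b)) exo <- c(exo, b)
    if (in_ring(b) && !in_ring(a)) exo <- c(exo, a)
  }
  keep <- sort(unique(c(ring_atoms, exo)))
  # bonds that hold a ring system together: ring bonds and double (or higher)
  # bonds between kept atoms; acyclic single linkers (biphenyl-type) split
  keep_bond <- (is_ring_bond |
                  (mol$bonds$order >= 2L & mol$bonds$a1 %in% keep &
                     mol$bonds$a2 %in% keep))
  red <- mol
  red$bonds <- mol$bonds[keep_bond, , drop = FALSE]
  # hydrogens for bonds severed between kept atoms
  sev <- mol$bonds[!keep_bond, , drop = FALSE]
  for (k in seq_len(nrow(sev))) {
    for (a in c(sev$a1[k], sev$a2[k]))
      if (a %in% keep) red$atoms$nH[a] <- red$atoms$nH[a] + sev$order[k]
  }
  comps <- .mol_components(red)
  comps <- Filter(function(idx) any(idx %in% ring_atoms), comps)
  comps <- lapply(comps, intersect, keep)
  systems <- lapply(comps, function(idx) mol_subgraph(red, idx, id = mol$id))
  smis <- vapply(systems, canonical_smiles, character(1))
  systems <- systems[order(smis)]
  lapply(seq_along(systems), function(k) {
    m <- systems[[k]]
    m$id <- if (length(systems) == 1L) paste0(mol$id, "_rs") else
      paste0(mol$id, "_rs", k)
    ring_system(m, ring_id = m$id)
  })
}
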