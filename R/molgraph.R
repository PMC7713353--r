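# Internal molecular-graph representation.
#
# A `trmol` stores the heavy-atom graph of one molecule: element, formal
# charge and attached-hydrogen count per atom, bonds with (kekulized) order,
# and optional 3D coordinates.  Parsing of the standard formats is delegated
# to OpenBabel through ChemmineR/ChemmineOB; this class only normalizes the
# parsed structure (explicit hydrogens are folded into per-atom H counts).

#' Construct a molecule record
#'
#' Low-level constructor for the molecular-graph objects used throughout the
#' package.  Most users obtain these from [parse_structures()] or
#' [smiles_to_mol()] rather than building them by hand.
#'
#' @param atoms data frame with columns `elem` (element symbol), `charge`
#'   (integer formal charge) and `nH` (attached hydrogen count).
#' @param bonds data frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (integer bond order; kekulized, so 1/2/3).
#' @param coords optional numeric matrix (one row per atom, columns x/y/z, in
#'   Angstrom).
#' @param id molecule identifier (unique within a collection).
#' @param source free-text provenance tag.
#' @return An object of class `trmol`.
#' @export
trmol <- function(atoms, bonds, coords = NULL, id = "mol", source = "") {
  stopifnot(is.data.frame(atoms), all(c("elem", "charge", "nH") %in% names(atoms)))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  bonds <- as.data.frame(bonds)[, c("a1", "a2", "order")]
  n <- nrow(atoms)
  if (nrow(bonds) && (max(bonds$a1, bonds$a2) > n || min(bonds$a1, bonds$a2) < 1L))
    stop("bond table references atoms outside 1..", n)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L)
      stop("coords must be an n x 3 matrix (one triple per atom)")
    if (!all(is.finite(coords))) stop("coords must be finite")
  }
  structure(list(id = as.character(id),
                 atoms = data.frame(elem = as.character(atoms$elem),
                                    charge = as.integer(atoms$charge),
                                    nH = as.integer(atoms$nH)),
                 bonds = data.frame(a1 = as.integer(bonds$a1),
                                    a2 = as.integer(bonds$a2),
                                    order = as.integer(bonds$order)),
                 coords = coords,
                 source = as.character(source)),
            class = "trmol")
}

#' @export
print.trmol <- function(x, ...) {
  cat(sprintf("<trmol %s> %s, %d heavy atoms, %d bonds%s\n",
              x$id, mol_formula_string(x), nrow(x$atoms), nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 3D"))
  invisible(x)
}

n_heavy_atoms <- function(mol) nrow(mol$atoms)

# implicit hydrogen count for one atom given its bond-order sum
.implicit_h <- function(elem, charge, bondsum) {
  vals <- .element_valences[[elem]]
  if (is.null(vals)) return(0L)
  eff <- switch(elem,
                C = vals - abs(charge),
                B = vals - charge,
                vals + charge)
  for (v in sort(eff)) if (v >= bondsum) return(as.integer(v - bondsum))
  0L
}

# --- conversion from ChemmineR SDF objects -------------------------------

.mdl_charge <- function(code) {
  # MDL legacy charge codes: 1 = +3 ... 3 = +1, 5 = -1 ... 7 = -3
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(as.integer(code))]
  out[is.na(out)] <- 0L
  unname(out)
}

sdf_to_trmol <- function(sdf, id = NULL, source = "sdf") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(id)) {
    id <- ChemmineR::sdfid(sdf)
    if (!length(id) || is.na(id) || !nzchar(id)) id <- "mol"
  }
  elems <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charge <- if ("C6" %in% colnames(ab)) .mdl_charge(ab[, "C6"]) else
    rep(0L, nrow(ab))
  if (is.null(dim(bb)) || nrow(as.matrix(bb)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bb <- as.matrix(bb)
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  n <- length(elems)
  bondsum <- numeric(n)
  hexp <- integer(n)
  ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)  # tolerate aromatic order
  for (k in seq_len(nrow(bonds))) {
    bondsum[bonds$a1[k]] <- bondsum[bonds$a1[k]] + ord[k]
    bondsum[bonds$a2[k]] <- bondsum[bonds$a2[k]] + ord[k]
  }
  bondsum <- round(bondsum)
  is_h <- elems == "H"
  if (any(is_h)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      if (is_h[a] && !is_h[b]) hexp[b] <- hexp[b] + 1L
      if (is_h[b] && !is_h[a]) hexp[a] <- hexp[a] + 1L
    }
  }
  nH <- vapply(seq_len(n), function(i) {
    if (is_h[i]) 0L else .implicit_h(elems[i], charge[i], bondsum[i]) + hexp[i]
  }, integer(1))
  keep <- which(!is_h)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  bkeep <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
  bkeep$a1 <- remap[bkeep$a1]; bkeep$a2 <- remap[bkeep$a2]
  has3d <- any(abs(coords[, 3]) > 1e-8)
  trmol(atoms = data.frame(elem = elems[keep], charge = charge[keep],
                           nH = nH[keep]),
        bonds = bkeep,
        coords = if (has3d) coords[keep, , drop = FALSE] else NULL,
        id = id, source = source)
}

#' Parse SMILES strings into molecule records
#'
#' @param smiles character vector of SMILES (names, if present, become ids).
#' @param source provenance tag stored on each record.
#' @return A list of `trmol` objects.
#' @export
smiles_to_mol <- function(smiles, source = "smiles") {
  if (!length(smiles)) return(list())
  nms <- names(smiles)
  if (is.null(nms)) nms <- paste0("mol", seq_along(smiles))
  nms[!nzchar(nms)] <- paste0("mol", which(!nzchar(nms)))
  sdfset <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(as.character(smiles), nms)))
  out <- lapply(seq_along(sdfset), function(i) {
    m <- tryCatch(sdf_to_trmol(sdfset[[i]], id = nms[i], source = source),
                  error = function(e) NULL)
    # ChemmineR cannot represent single-atom molecules; handle those directly
    if (is.null(m)) m <- .single_atom_mol(smiles[[i]], nms[i], source)
    if (is.null(m)) stop("cannot parse SMILES: ", smiles[[i]])
    m
  })
  names(out) <- nms
  out
}

# single heavy atom SMILES such as "C", "[Br-]", "[NH4+]"
.single_atom_mol <- function(smi, id, source) {
  m <- regmatches(smi, regexec(
    "^\\[?([A-Z][a-z]?)(H([0-9]*))?(([+-])([0-9]*))?\\]?$", trimws(smi)))[[1]]
  if (!length(m) || !m[2] %in% rownames(.element_data)) return(NULL)
  charge <- 0L
  if (nzchar(m[6]))
    charge <- as.integer(paste0(m[6], if (nzchar(m[7])) m[7] else "1"))
  nH <- if (nzchar(m[3])) {
    if (nzchar(m[4])) as.integer(m[4]) else 1L
  } else if (grepl("^\\[", trimws(smi))) 0L else
    .implicit_h(m[2], charge, 0)
  trmol(atoms = data.frame(elem = m[2], charge = charge, nH = nH),
        bonds = NULL, id = id, source = source)
}

# --- SDF writing / round-trips -------------------------------------------

# Minimal V2000 writer for trmol objects (used to hand structures back to
# OpenBabel for SMARTS matching, property calculation and canonicalization).
write_sdf_text <- function(mol, coords = NULL) {
  at <- mol$atoms; bd <- mol$bonds
  if (is.null(coords)) coords <- mol$coords
  if (is.null(coords)) coords <- matrix(0, nrow(at), 3)
  lines <- c(mol$id, " trscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(at), nrow(bd)))
  # legacy atom-block charge codes (in addition to M CHG): some readers
  # keep only the atom block
  legacy <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L,
              `-2` = 6L, `-3` = 7L)
  ccode <- legacy[as.character(at$charge)]
  ccode[is.na(ccode)] <- 0L
  lines <- c(lines, vapply(seq_len(nrow(at)), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], at$elem[i], ccode[i]),
    character(1)))
  if (nrow(bd))
    lines <- c(lines, vapply(seq_len(nrow(bd)), function(k)
      sprintf("%3d%3d%3d  0  0  0  0", bd$a1[k], bd$a2[k], bd$order[k]),
      character(1)))
  chg <- which(at$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, at$charge[grp]),
                                      collapse = "")))
    }
  }
  c(lines, "M  END", "$$$$")
}

# trmol list -> ChemmineR SDFset (via a temp file, so OpenBabel/ChemmineR
# remain the only SDF parsers in the package)
mols_to_sdfset <- function(mols) {
  if (inherits(mols, "trmol")) mols <- list(mols)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(unlist(lapply(mols, write_sdf_text)), tf)
  ChemmineR::read.SDFset(tf)
}

#' Canonical SMILES of a molecule record
#'
#' @param mol a `trmol` object.
#' @return A single canonical SMILES string (OpenBabel canonicalization).
#' @export
canonical_smiles <- function(mol) {
  txt <- paste0(paste(write_sdf_text(mol), collapse = "\n"), "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  strsplit(trimws(out), "[\t ]")[[1]][1]
}

# --- formula / mass helpers ----------------------------------------------

#' Molecular formula as element counts
#'
#' @param mol a `trmol` object.
#' @return Named integer vector of element counts, hydrogens included.
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$elem)
  out <- stats::setNames(as.integer(counts), names(counts))
  hn <- sum(mol$atoms$nH)
  out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + hn
  out <- out[out > 0]
  # Hill order: C, H, then alphabetical
  pref <- c("C", "H")
  ord <- c(intersect(pref, names(out)), sort(setdiff(names(out), pref)))
  out[ord]
}

mol_formula_string <- function(mol) {
  f <- mol_formula(mol)
  paste0(names(f), ifelse(f > 1, f, ""), collapse = "")
}

#' Molecular weight from embedded standard atomic weights
#'
#' @param mol a `trmol` object.
#' @return Molecular weight in g/mol.
#' @export
mol_weight <- function(mol) {
  f <- mol_formula(mol)
  sum(.elem_lookup(names(f), "mass", "atomic mass") * f)
}

# adjacency as list of integer vectors
.mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# induced subgraph on a set of atom indices (preserves coords if present);
# hydrogens implied by severed bonds are restored on the cut atoms
mol_subgraph <- function(mol, atom_idx, id = mol$id) {
  atom_idx <- sort(unique(as.integer(atom_idx)))
  remap <- integer(nrow(mol$atoms)); remap[atom_idx] <- seq_along(atom_idx)
  keep_bond <- mol$bonds$a1 %in% atom_idx & mol$bonds$a2 %in% atom_idx
  lost <- mol$bonds[!keep_bond, , drop = FALSE]
  at <- mol$atoms[atom_idx, , drop = FALSE]
  rownames(at) <- NULL
  for (k in seq_len(nrow(lost))) {
    for (a in c(lost$a1[k], lost$a2[k])) {
      if (a %in% atom_idx) {
        at$nH[remap[a]] <- at$nH[remap[a]] + lost$order[k]
      }
    }
  }
  bd <- mol$bonds[keep_bond, , drop = FALSE]
  bd$a1 <- remap[bd$a1]; bd$a2 <- remap[bd$a2]
  trmol(atoms = at, bonds = bd,
        coords = if (is.null(mol$coords)) NULL else
          mol$coords[atom_idx, , drop = FALSE],
        id = id, source = mol$source)
}

# connected components of the heavy-atom graph; list of index vectors
.mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(list())
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  comp <- igraph::components(g)$membership
  unname(split(seq_len(n), comp))
}
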