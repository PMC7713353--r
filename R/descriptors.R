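# Molecular descriptors feeding the ring-selection funnel.

#' Additive van der Waals molecular volume (VABC)
#'
#' Computes the approximate van der Waals volume (cubic Angstrom per
#' molecule) from additive atomic contributions with bond and ring
#' corrections:
#'
#' \deqn{V_{vdW} = \sum \mathrm{atom\ contributions} - 5.92 N_B - 14.7 R_A
#'   - 3.8 R_{NR}}
#'
#' where `N_B` is the number of bonds (hydrogens included), `R_A` the number
#' of aromatic rings and `R_NR` the number of non-aromatic rings (both over
#' the SSSR).  The per-element contributions are embedded
#' (see [element_table()]).
#'
#' @param mol a `trmol` object.
#' @return Volume in cubic Angstrom.
#' @examples
#' \dontrun{
#' compute_vabc(smiles_to_mol("C")[[1]])        # methane: 25.86
#' compute_vabc(smiles_to_mol("c1ccccc1")[[1]]) # benzene: 81.18
#' }
#' @export
compute_vabc <- function(mol) {
  if (inherits(mol, "ring_system")) mol <- mol$mol
  contrib <- sum(.elem_lookup(mol$atoms$elem, "vabc", "atomic contribution")) +
    7.24 * sum(mol$atoms$nH)
  n_bonds <- nrow(mol$bonds) + sum(mol$atoms$nH)
  rs <- mol_rings(mol)
  r_arom <- sum(rs$aromatic)
  r_nonarom <- length(rs$rings) - r_arom
  contrib - 5.92 * n_bonds - 14.7 * r_arom - 3.8 * r_nonarom
}

#' Fragment complexity descriptor
#'
#' `|B^2 - A^2 + A| + H/100` with `B` the number of heavy-atom--heavy-atom
#' bonds, `A` the number of heavy atoms and `H` the number of heteroatoms
#' (heavy atoms other than carbon).
#'
#' @param mol a `trmol` object.
#' @return Numeric complexity value.
#' @export
compute_fragment_complexity <- function(mol) {
  if (inherits(mol, "ring_system")) mol <- mol$mol
  A <- nrow(mol$atoms)
  B <- nrow(mol$bonds)
  H <- sum(!mol$atoms$elem %in% c("C", "H"))
  abs(B^2 - A^2 + A) + H / 100
}

# Versioned hydrogen-bond atom pattern sets (SMARTS, matched by OpenBabel).
# Donors: N or O bearing at least one hydrogen.  Acceptors: N or O, excluding
# pyrrole-type aromatic NH and positively charged nitrogen.
.hbond_smarts <- list(
  donor = c("[#7;!H0]", "[#8;!H0]"),
  acceptor = c("[#7;!$([nH]);!$([#7+])]", "[#8]")
)

#' Count hydrogen-bond donor and acceptor atoms
#'
#' Matches the package's fixed, versioned SMARTS lists (see
#' `trscreen:::.hbond_smarts`) so counts are reproducible across releases.
#' Counts are invariant to atom ordering.
#'
#' @param mol a `trmol` object (or a list of them, for vectorized use).
#' @return For one molecule, a named integer vector `c(hba=, hbd=)`; for a
#'   list, a two-column matrix.
#' @export
count_hbond_atoms <- function(mol) {
  single <- inherits(mol, "trmol") || inherits(mol, "ring_system")
  mols <- if (single) list(mol) else mol
  mols <- lapply(mols, function(m) if (inherits(m, "ring_system")) m$mol else m)
  sdfset <- mols_to_sdfset(mols)
  countp <- function(patterns) {
    m <- vapply(patterns, function(p)
      as.numeric(ChemmineR::smartsSearchOB(sdfset, p, uniqueMatches = TRUE)),
      numeric(length(mols)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(mols))
    rowSums(m)
  }
  res <- cbind(hba = as.integer(countp(.hbond_smarts$acceptor)),
               hbd = as.integer(countp(.hbond_smarts$donor)))
  if (single) res[1, ] else res
}

#' Full descriptor set for one molecule
#'
#' @param mol a `trmol` or `ring_system` object.
#' @return An object of class `descriptor_set`: a one-row data frame with
#'   columns `vabc`, `n_bonds`, `n_aromatic_rings`, `n_nonaromatic_rings`,
#'   `fragment_complexity`, `hba`, `hbd`, `mw`.
#' @export
descriptor_set <- function(mol) {
  m <- if (inherits(mol, "ring_system")) mol$mol else mol
  rs <- mol_rings(m)
  hb <- count_hbond_atoms(m)
  out <- data.frame(
    vabc = compute_vabc(m),
    n_bonds = nrow(m$bonds) + sum(m$atoms$nH),
    n_aromatic_rings = sum(rs$aromatic),
    n_nonaromatic_rings = length(rs$rings) - sum(rs$aromatic),
    fragment_complexity = compute_fragment_complexity(m),
    hba = hb[["hba"]], hbd = hb[["hbd"]],
    mw = mol_weight(m)
  )
  class(out) <- c("descriptor_set", class(out))
  out
}

#' Write a descriptor table for a set of ring systems
#'
#' @param rings list of `ring_system` objects.
#' @param descriptors optional list of `descriptor_set` rows (computed when
#'   missing).
#' @param path output CSV path (columns: id, vabc, fragment_complexity, hba,
#'   hbd, mw, n_rings, frequency).
#' @return The table, invisibly.
#' @export
write_descriptor_table <- function(rings, descriptors = NULL, path) {
  if (is.null(descriptors))
    descriptors <- lapply(rings, function(r) descriptor_set(r$mol))
  tab <- do.call(rbind, lapply(seq_along(rings), function(i) {
    d <- descriptors[[i]]
    data.frame(id = rings[[i]]$ring_id, vabc = d$vabc,
               fragment_complexity = d$fragment_complexity,
               hba = d$hba, hbd = d$hbd, mw = d$mw,
               n_rings = rings[[i]]$n_rings,
               frequency = rings[[i]]$frequency)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
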