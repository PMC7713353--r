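# Combinatorial N-arylation library growth and drug-likeness scoring.
#
# The chosen ring system (demethylated at its amine) is the core; products
# are formed in silico as the Buchwald-Hartwig-type coupling outcome: a new
# N-C bond between the core's attachment nitrogen and the reagent carbon
# bearing the bromide, with loss of HBr.

#' Define a core scaffold with a growth site
#'
#' @param mol `trmol` of the core (e.g. the demethylated ring system).
#' @param attachment_atom index of the growth-site atom; must bear at least
#'   one hydrogen, and the core must contain at least one ring.
#' @param note free-text provenance note.
#' @return An object of class `core_scaffold`.
#' @export
core_scaffold <- function(mol, attachment_atom, note = "") {
  attachment_atom <- as.integer(attachment_atom)
  stopifnot(attachment_atom >= 1, attachment_atom <= nrow(mol$atoms))
  if (mol$atoms$nH[attachment_atom] < 1L)
    stop("attachment atom must bear at least one hydrogen")
  if (count_rings(mol) < 1L)
    stop("core must contain at least one ring")
  structure(list(mol = mol, attachment_atom = attachment_atom, note = note),
            class = "core_scaffold")
}

# index of the unique qualifying C-Br (aryl or vinyl carbon), or NULL
.find_aryl_vinyl_bromide <- function(mol) {
  rs <- mol_rings(mol)
  arom_atoms <- unique(unlist(rs$rings[rs$aromatic]))
  hits <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    br <- if (mol$atoms$elem[a] == "Br") a else
      if (mol$atoms$elem[b] == "Br") b else next
    cc <- if (br == a) b else a
    if (mol$atoms$elem[cc] != "C") next
    aryl <- cc %in% arom_atoms
    vinyl <- any((mol$bonds$a1 == cc | mol$bonds$a2 == cc) &
                   mol$bonds$order == 2L &
                   mol$atoms$elem[ifelse(mol$bonds$a1 == cc, mol$bonds$a2,
                                         mol$bonds$a1)] == "C")
    if (aryl || vinyl) hits[[length(hits) + 1L]] <- c(br = br, c = cc)
  }
  if (length(hits) != 1L) return(NULL)
  hits[[1]]
}

#' Define an N-arylation reagent
#'
#' @param mol `trmol` of an aryl or vinyl bromide; must carry exactly one
#'   C-Br whose carbon is aromatic or vinylic.
#' @return An object of class `reagent`.
#' @export
reagent_record <- function(mol) {
  hit <- .find_aryl_vinyl_bromide(mol)
  if (is.null(hit))
    stop("reagent ", mol$id,
         " lacks a unique aryl/vinyl C-Br leaving group")
  structure(list(mol = mol, br_atom = hit[["br"]], c_atom = hit[["c"]]),
            class = "reagent")
}

# join core and reagent: new N-C bond, lose Br and one N-H
.couple <- function(core, rg, id) {
  cm <- core$mol; rm <- rg$mol
  nc <- nrow(cm$atoms)
  keep_r <- setdiff(seq_len(nrow(rm$atoms)), rg$br_atom)
  remap <- integer(nrow(rm$atoms)); remap[keep_r] <- nc + seq_along(keep_r)
  at <- rbind(cm$atoms, rm$atoms[keep_r, , drop = FALSE])
  at$nH[core$attachment_atom] <- at$nH[core$attachment_atom] - 1L
  rb <- rm$bonds[rm$bonds$a1 != rg$br_atom & rm$bonds$a2 != rg$br_atom, ,
                 drop = FALSE]
  rb$a1 <- remap[rb$a1]; rb$a2 <- remap[rb$a2]
  bd <- rbind(cm$bonds, rb,
              data.frame(a1 = core$attachment_atom,
                         a2 = remap[rg$c_atom], order = 1L))
  trmol(atoms = at, bonds = bd, id = id, source = "enumerated")
}

# count rotatable bonds: acyclic single bonds between non-terminal heavy
# atoms, excluding amide C-N
.count_rotatable <- function(mol) {
  if (!nrow(mol$bonds)) return(0L)
  enum <- .enumerate_rings(mol)
  ring_edges <- unique(unlist(lapply(enum$rings, .ring_edges)))
  deg <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds$a1[k]] <- deg[mol$bonds$a1[k]] + 1L
    deg[mol$bonds$a2[k]] <- deg[mol$bonds$a2[k]] + 1L
  }
  is_amide_cn <- function(a, b) {
    # C(=O)-N in either orientation
    for (p in list(c(a, b), c(b, a))) {
      cc <- p[1]; nn <- p[2]
      if (mol$atoms$elem[cc] == "C" && mol$atoms$elem[nn] == "N") {
        has_o <- any((mol$bonds$a1 == cc | mol$bonds$a2 == cc) &
                       mol$bonds$order == 2L &
                       mol$atoms$elem[ifelse(mol$bonds$a1 == cc,
                                             mol$bonds$a2,
                                             mol$bonds$a1)] == "O")
        if (has_o) return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (mol$bonds$order[k] != 1L) next
    eid <- paste(min(a, b), max(a, b), sep = "-")
    if (eid %in% ring_edges) next
    if (deg[a] < 2L || deg[b] < 2L) next
    if (is_amide_cn(a, b)) next
    n <- n + 1L
  }
  n
}

# OpenBabel bulk properties (logP, TPSA, MW) for a list of trmols
.ob_props <- function(mols) {
  # trailing newline required for OpenBabel to see the final record
  txt <- paste0(paste(unlist(lapply(mols, write_sdf_text)),
                      collapse = "\n"), "\n")
  res <- ChemmineOB::forEachMol("SDF", txt, ChemmineOB::prop_OB)
  if (is.data.frame(res)) res else do.call(rbind, res)
}

#' Topological polar surface area
#'
#' Polar surface area from the standard published per-fragment contribution
#' scheme (Ertl TPSA as implemented in OpenBabel), in square Angstrom.
#' This is a topological approximation of 3D polar surface areas computed
#' by commercial predictors; absolute values differ from those.
#'
#' @param mol a `trmol` object.
#' @return PSA in square Angstrom.
#' @export
compute_psa <- function(mol) {
  .ob_props(list(mol))$TPSA[1]
}

#' Ligand efficiency
#'
#' Docking score divided by heavy-atom count (kcal/mol per heavy atom).
#'
#' @param docking_score docking score (kcal/mol; more negative = better).
#' @param mol a `trmol` object (heavy-atom count taken from its graph).
#' @return Ligand efficiency (rounded only for display).
#' @export
ligand_efficiency <- function(docking_score, mol) {
  n <- n_heavy_atoms(mol)
  if (n < 1L) stop("ligand efficiency undefined for zero heavy atoms")
  docking_score / n
}

# Curated, versioned subset of the published pan-assay interference (PAINS)
# substructure catalog, as OpenBabel SMARTS.  The full catalog is much
# larger; this subset covers the canonical high-frequency families.
.pains_smarts <- c(
  quinone_para = "O=C1C=CC(=O)C=C1",
  quinone_ortho = "O=C1C=CC=CC1=O",
  catechol = "[OX2H]c1c([OX2H])cccc1",
  rhodanine = "O=C1CSC(=S)N1",
  ene_rhodanine = "O=C1C(=C)SC(=S)N1",
  hydroxyphenyl_hydrazone = "[OX2H]c1ccccc1C=NN",
  azo_aromatic = "cN=Nc",
  isothiazolone = "O=C1C=CSN1",
  alkylidene_barbiturate = "O=C1NC(=O)NC(=O)C1=C",
  alkylidene_rhodanine_ox = "O=C1C(=C)SC(=O)N1",
  phenolic_mannich = "[OX2H]c1ccccc1CN(C)C",
  thiourea_enamine = "S=C(N)N",
  nitroso = "[#6][NX2]=O",
  beta_keto_phenol = "[OX2H]c1ccccc1C(=O)C=C"
)

#' PAINS substructure filter
#'
#' Evaluates the package's embedded, versioned subset of the published
#' pan-assay interference substructure catalog; a compound passes when no
#' pattern matches.
#'
#' @param mols a `trmol` or list of them.
#' @return Logical vector (`TRUE` = pass), named by molecule id.
#' @export
pains_filter <- function(mols) {
  if (inherits(mols, "trmol")) mols <- list(mols)
  sdfset <- mols_to_sdfset(mols)
  hits <- rep(0, length(mols))
  for (p in .pains_smarts) {
    hits <- hits + as.numeric(
      ChemmineR::smartsSearchOB(sdfset, p, uniqueMatches = TRUE))
  }
  stats::setNames(hits == 0, vapply(mols, function(m) m$id, character(1)))
}

.protonated_amide_smarts <- "[NX4+;H1,H2,H3][CX3]=[OX1]"

#' Enumerate an N-arylation library
#'
#' Forms one product per compatible reagent: the bond is made between the
#' core's attachment nitrogen and the reagent carbon bearing the bromide;
#' Br and one N-H are removed, so
#' `formula(product) + HBr = formula(core) + formula(reagent)`.
#' Reagents without a qualifying C-Br are skipped with a logged reason.
#'
#' @param core a `core_scaffold`.
#' @param reagents list of `reagent` objects or `trmol`s (coerced; a `trmol`
#'   without a unique aryl/vinyl C-Br is skipped).
#' @return A list of `product_record` objects with computed properties; the
#'   `skipped` attribute names rejected reagents.
#' @export
enumerate_n_arylation <- function(core, reagents) {
  skipped <- character()
  prods <- list()
  for (rg in reagents) {
    if (inherits(rg, "trmol")) {
      rg2 <- tryCatch(reagent_record(rg), error = function(e) NULL)
      if (is.null(rg2)) {
        warning("skipping reagent without qualifying C-Br: ", rg$id)
        skipped <- c(skipped, rg$id)
        next
      }
      rg <- rg2
    }
    id <- paste0(core$mol$id, "~", rg$mol$id)
    prods[[length(prods) + 1L]] <- list(rg = rg, mol = .couple(core, rg, id))
  }
  if (!length(prods)) {
    out <- list()
    attr(out, "skipped") <- skipped
    return(out)
  }
  mols <- lapply(prods, `[[`, "mol")
  props <- .ob_props(mols)
  pains <- pains_filter(mols)
  sdfset <- mols_to_sdfset(mols)
  prot_amide <- as.numeric(ChemmineR::smartsSearchOB(
    sdfset, .protonated_amide_smarts, uniqueMatches = TRUE)) > 0
  hb <- count_hbond_atoms(mols)
  out <- lapply(seq_along(prods), function(i) {
    m <- mols[[i]]
    mw <- mol_weight(m); logp <- props$logP[i]
    hba <- hb[i, "hba"]; hbd <- hb[i, "hbd"]
    rotb <- .count_rotatable(m)
    ro5 <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)
    ro3 <- sum(mw > 300, logp > 3, hbd > 3, hba > 3, rotb > 3)
    structure(list(mol = m, core_id = core$mol$id,
                   reagent_id = prods[[i]]$rg$mol$id,
                   heavy_atom_count = n_heavy_atoms(m),
                   mw = mw, logp = logp, psa = props$TPSA[i],
                   rotatable_bonds = rotb,
                   ro5_violations = as.integer(ro5),
                   ro3_violations = as.integer(ro3),
                   pains_pass = unname(pains[i]),
                   protonated_amide = prot_amide[i],
                   docking_score = NA_real_,
                   ligand_efficiency = NA_real_),
              class = "product_record")
  })
  names(out) <- vapply(mols, function(m) m$id, character(1))
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.product_record <- function(x, ...) {
  cat(sprintf(
    "<product %s> %s, %d heavy atoms, Ro5 viol %d, Ro3 viol %d, PAINS %s\n",
    x$mol$id, mol_formula_string(x$mol), x$heavy_atom_count,
    x$ro5_violations, x$ro3_violations, ifelse(x$pains_pass, "pass", "FAIL")))
  invisible(x)
}

#' Attach a docking score and ligand efficiency to a product
#'
#' @param product a `product_record`.
#' @param docking_score score in kcal/mol.
#' @return The updated `product_record`.
#' @export
score_product <- function(product, docking_score) {
  product$docking_score <- docking_score
  product$ligand_efficiency <- ligand_efficiency(docking_score, product$mol)
  product
}

#' Drug-likeness filter for enumerated products
#'
#' Keeps products with Lipinski rule-of-five violations `< ro5_max`,
#' fragment rule-of-three violations `< ro3_max`, and no protonated amide.
#' hERG and oral-absorption criteria are applied only when an external
#' predictor adapter supplies the values (columns `herg` / `oral` in
#' `predicted`); otherwise those criteria are skipped with a notice.
#'
#' @param products list of `product_record`s.
#' @param ro5_max strict bound on rule-of-five violations (default 2).
#' @param ro3_max strict bound on rule-of-three violations (default 1).
#' @param predicted optional data frame (rownames = product ids) with
#'   external predictor columns `herg`, `oral`.
#' @param herg_min,oral_min thresholds applied when predictions exist.
#' @return list with `kept` products and a `filter_report`.
#' @export
druglikeness_filter <- function(products, ro5_max = 2, ro3_max = 1,
                                predicted = NULL, herg_min = -5,
                                oral_min = 80) {
  ids <- vapply(products, function(p) p$mol$id, character(1))
  reason <- rep(NA_character_, length(products))
  ro5 <- vapply(products, function(p) p$ro5_violations, integer(1))
  ro3 <- vapply(products, function(p) p$ro3_violations, integer(1))
  pa <- vapply(products, function(p) p$protonated_amide, logical(1))
  reason[ro5 >= ro5_max] <- sprintf("Ro5 violations >= %d", ro5_max)
  reason[is.na(reason) & ro3 >= ro3_max] <-
    sprintf("Ro3 violations >= %d", ro3_max)
  reason[is.na(reason) & pa] <- "protonated amide"
  if (!is.null(predicted)) {
    if ("herg" %in% colnames(predicted)) {
      v <- predicted[ids, "herg"]
      reason[is.na(reason) & !is.na(v) & v < herg_min] <-
        sprintf("hERG < %g", herg_min)
    }
    if ("oral" %in% colnames(predicted)) {
      v <- predicted[ids, "oral"]
      reason[is.na(reason) & !is.na(v) & v <= oral_min] <-
        sprintf("oral <= %g", oral_min)
    }
  } else {
    message("no external predictor values; hERG/oral criteria skipped")
  }
  pass <- is.na(reason)
  list(kept = products[pass],
       report = filter_report("druglikeness", ids, pass, reason))
}
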