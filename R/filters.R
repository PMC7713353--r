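# Declarative, reportable selection funnels for ring systems, targets and
# co-crystal ligands.
#
# All printed inequalities are read strictly as written (vabc > 140,
# HA + HB < 3, ligand count > 100, "more than five PDBs" = at least 6);
# closed molecular-weight windows include their endpoints.  Every threshold
# is an argument, so the boundaries are documented and configurable.

#' Per-stage filter report
#'
#' @param stage stage name.
#' @param ids item identifiers entering the stage.
#' @param pass logical pass flag per item.
#' @param reason first failing criterion per item (`NA` for passing items).
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(stage, ids, pass, reason = NA_character_) {
  stopifnot(length(ids) == length(pass))
  structure(list(stage = stage,
                 n_in = length(ids), n_out = sum(pass),
                 items = data.frame(id = as.character(ids), pass = pass,
                                    reason = ifelse(pass, NA_character_,
                                                    reason))),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d\n", x$stage, x$n_in, x$n_out))
  invisible(x)
}

#' Summarize a funnel (list of filter reports)
#'
#' @param funnel list of `filter_report` objects.
#' @return Data frame with columns stage, n_in, n_out.
#' @export
funnel_summary <- function(funnel) {
  do.call(rbind, lapply(funnel, function(r)
    data.frame(stage = r$stage, n_in = r$n_in, n_out = r$n_out)))
}

#' Descriptor-based ring-system selection funnel
#'
#' Applies, in order: frequency < `freq_max_exclusive` (rarely used rings),
#' additive van der Waals volume > `vabc_min` (strictly larger than a
#' benzene ring), and hydrogen-bond atom sum `hba + hbd <
#' hahb_max_exclusive`.  A ring with a missing descriptor fails with reason
#' `"missing descriptor"`.
#'
#' @param rings list of `ring_system` objects.
#' @param descriptors list of `descriptor_set` rows, parallel to `rings`
#'   (computed on the ring systems themselves when `NULL`).
#' @param vabc_min strict lower volume bound (default 140).
#' @param hahb_max_exclusive strict upper bound on hba + hbd (default 3).
#' @param freq_max_exclusive strict upper bound on drug frequency (default 3).
#' @return list with `kept` (ring list), `descriptors` (parallel), and
#'   `funnel` (list of `filter_report`s, one per stage).
#' @export
filter_ring_systems <- function(rings, descriptors = NULL, vabc_min = 140,
                                hahb_max_exclusive = 3,
                                freq_max_exclusive = 3) {
  if (is.null(descriptors))
    descriptors <- lapply(rings, function(r) descriptor_set(r$mol))
  ids <- vapply(rings, function(r) r$ring_id, character(1))
  getd <- function(d, f) if (is.null(d) || is.null(d[[f]]) ||
                             is.na(d[[f]])) NA_real_ else d[[f]]
  funnel <- list()
  keep <- seq_along(rings)

  stage <- function(name, value, test, reason) {
    v <- value[keep]
    ok <- !is.na(v) & test(v)
    rsn <- ifelse(is.na(v), "missing descriptor", reason)
    rep <- filter_report(name, ids[keep], ok, rsn)
    keep <<- keep[ok]
    funnel[[length(funnel) + 1L]] <<- rep
  }

  freq <- vapply(rings, function(r) as.numeric(r$frequency), numeric(1))
  vabc <- vapply(descriptors, getd, numeric(1), f = "vabc")
  hahb <- vapply(descriptors, function(d) {
    a <- getd(d, "hba"); b <- getd(d, "hbd"); a + b
  }, numeric(1))

  stage("frequency", freq, function(v) v < freq_max_exclusive,
        sprintf("frequency >= %d", freq_max_exclusive))
  stage("vabc", vabc, function(v) v > vabc_min,
        sprintf("vabc <= %g", vabc_min))
  stage("hahb", hahb, function(v) v < hahb_max_exclusive,
        sprintf("hba+hbd >= %d", hahb_max_exclusive))

  list(kept = rings[keep], descriptors = descriptors[keep], funnel = funnel)
}

#' Construct a target record
#'
#' @param uniprot accession string.
#' @param pdb_ids character vector of PDB codes (duplicates are removed).
#' @param ligands list of `trmol` co-crystal ligands (optionally 3D).
#' @param development_label one of `"research"`, `"clinical"`,
#'   `"successful"`, `"unknown"`.
#' @param chembl_ligand_count number of known ligands.
#' @param in_clinical_table,in_ligand_table membership flags for the
#'   clinical-target and known-ligand tables (the package does not query
#'   databases).
#' @return An object of class `target_record`.
#' @export
target_record <- function(uniprot, pdb_ids = character(), ligands = list(),
                          development_label = c("unknown", "research",
                                                "clinical", "successful"),
                          chembl_ligand_count = 0L,
                          in_clinical_table = FALSE,
                          in_ligand_table = FALSE) {
  development_label <- match.arg(development_label)
  structure(list(uniprot = as.character(uniprot),
                 pdb_ids = unique(as.character(pdb_ids)),
                 ligands = ligands,
                 development_label = development_label,
                 chembl_ligand_count = as.integer(chembl_ligand_count),
                 in_clinical_table = isTRUE(in_clinical_table),
                 in_ligand_table = isTRUE(in_ligand_table)),
            class = "target_record")
}

#' @export
print.target_record <- function(x, ...) {
  cat(sprintf("<target %s> %d PDB(s), %d ligand(s), %s, %d known ligands\n",
              x$uniprot, length(x$pdb_ids), length(x$ligands),
              x$development_label, x$chembl_ligand_count))
  invisible(x)
}

# representative co-crystal ligand: most frequent canonical structure among
# the qualifying ligands, ties broken lexicographically
.representative_ligand <- function(ligands) {
  if (!length(ligands)) return(NULL)
  smis <- vapply(ligands, canonical_smiles, character(1))
  tab <- sort(table(smis), decreasing = TRUE)
  best <- names(tab)[tab == max(tab)]
  ligands[[which(smis == sort(best)[1])[1]]]
}

.ligand_has_carbon <- function(mol) any(mol$atoms$elem == "C")

#' Criteria-based target selection funnel
#'
#' Applies, in order: more than `min_pdbs - 1` deposited PDBs (strict
#' reading of "more than five"), at least one co-crystal ligand, a
#' carbon-containing ligand, ligand molecular weight within `ligand_mw`,
#' membership in the clinical-target and known-ligand tables, known-ligand
#' count > `chembl_min_exclusive`, then representative-ligand properties:
#' MW within `rep_mw`, HBA < `hba_max_exclusive`, HBD < `hbd_max_exclusive`.
#' Failures are reported, never raised.
#'
#' @param targets list of `target_record` objects.
#' @param min_pdbs minimum PDB count (default 6).
#' @param ligand_mw closed MW window a co-crystal ligand must fall in.
#' @param chembl_min_exclusive strict lower bound on known-ligand count.
#' @param rep_mw closed MW window for the representative ligand.
#' @param hba_max_exclusive,hbd_max_exclusive strict upper bounds on the
#'   representative ligand's hydrogen-bond atom counts.
#' @return list with `kept` (target list) and `funnel` (filter reports).
#' @export
filter_targets <- function(targets, min_pdbs = 6, ligand_mw = c(250, 800),
                           chembl_min_exclusive = 100, rep_mw = c(200, 700),
                           hba_max_exclusive = 5, hbd_max_exclusive = 2) {
  ids <- vapply(targets, function(t) t$uniprot, character(1))
  funnel <- list()
  keep <- seq_along(targets)

  stage <- function(name, ok_all, reason) {
    ok <- ok_all[keep]
    rep <- filter_report(name, ids[keep], ok, reason)
    keep <<- keep[ok]
    funnel[[length(funnel) + 1L]] <<- rep
  }

  qualifying <- lapply(targets, function(t) {
    Filter(function(l) .ligand_has_carbon(l) &&
             mol_weight(l) >= ligand_mw[1] && mol_weight(l) <= ligand_mw[2],
           t$ligands)
  })
  rep_lig <- lapply(qualifying, .representative_ligand)

  stage("pdb_count",
        vapply(targets, function(t) length(t$pdb_ids) >= min_pdbs, logical(1)),
        sprintf("fewer than %d PDBs", min_pdbs))
  stage("has_ligand",
        vapply(targets, function(t) length(t$ligands) > 0, logical(1)),
        "no co-crystal ligand")
  stage("ligand_carbon",
        vapply(targets, function(t)
          any(vapply(t$ligands, .ligand_has_carbon, logical(1))), logical(1)),
        "no carbon-containing ligand")
  stage("ligand_mw",
        vapply(qualifying, function(q) length(q) > 0, logical(1)),
        sprintf("no ligand with MW in [%g, %g]", ligand_mw[1], ligand_mw[2]))
  stage("clinical_table",
        vapply(targets, function(t) t$in_clinical_table, logical(1)),
        "not in clinical-target table")
  stage("ligand_table",
        vapply(targets, function(t) t$in_ligand_table, logical(1)),
        "not in known-ligand table")
  stage("chembl_count",
        vapply(targets, function(t)
          t$chembl_ligand_count > chembl_min_exclusive, logical(1)),
        sprintf("ligand count <= %g", chembl_min_exclusive))

  rep_ok <- function(f) vapply(seq_along(targets), function(i) {
    l <- rep_lig[[i]]
    !is.null(l) && f(l)
  }, logical(1))
  stage("rep_mw", rep_ok(function(l) {
    w <- mol_weight(l); w >= rep_mw[1] && w <= rep_mw[2]
  }), sprintf("representative ligand MW outside [%g, %g]",
              rep_mw[1], rep_mw[2]))
  stage("rep_hba", rep_ok(function(l)
    count_hbond_atoms(l)[["hba"]] < hba_max_exclusive),
    sprintf("representative ligand HBA >= %d", hba_max_exclusive))
  stage("rep_hbd", rep_ok(function(l)
    count_hbond_atoms(l)[["hbd"]] < hbd_max_exclusive),
    sprintf("representative ligand HBD >= %d", hbd_max_exclusive))

  list(kept = targets[keep], funnel = funnel)
}

#' Filter PDB co-crystal ligands for the shape screen
#'
#' Removes ligands belonging to targets labeled `successful`, inorganic
#' (carbon-free) ligands, and ligands with molecular weight outside the
#' closed window `mw_range`.
#'
#' @param ligands list of `trmol` ligands.
#' @param labels development label per ligand (recycled if length 1).
#' @param mw_range closed molecular-weight window (default `c(250, 800)`).
#' @return list with `kept` ligands and a `filter_report`.
#' @export
filter_pdb_ligands <- function(ligands, labels = "unknown",
                               mw_range = c(250, 800)) {
  labels <- rep_len(as.character(labels), length(ligands))
  ids <- vapply(ligands, function(l) l$id, character(1))
  mw <- vapply(ligands, mol_weight, numeric(1))
  carbon <- vapply(ligands, .ligand_has_carbon, logical(1))
  reason <- rep(NA_character_, length(ligands))
  reason[labels == "successful"] <- "successful target"
  reason[is.na(reason) & !carbon] <- "inorganic (no carbon)"
  reason[is.na(reason) & (mw < mw_range[1] | mw > mw_range[2])] <-
    sprintf("MW outside [%g, %g]", mw_range[1], mw_range[2])
  pass <- is.na(reason)
  list(kept = ligands[pass],
       report = filter_report("pdb_ligands", ids, pass, reason))
}
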