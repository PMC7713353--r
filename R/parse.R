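# Structure input: SMILES files, SDF V2000 files, PDB HETATM blocks.

#' Parse a structure file into molecule records
#'
#' Reads molecules from one of the standard formats.  SMILES files hold one
#' molecule per line with an optional whitespace-separated id token; SDF
#' files are V2000 multi-record files; `pdb-het` extracts each HETATM
#' residue of a PDB file as a ligand (bonds perceived from interatomic
#' distances, since PDB carries no connection table for most ligands).
#'
#' Malformed entries are skipped with a warning and counted in the parse
#' report attached to the result (`attr(x, "report")`).
#'
#' @param path path to the input file.
#' @param format one of `"smiles"`, `"sdf"`, `"pdb-het"`.
#' @return A list of `trmol` records with a `report` attribute
#'   (`n_read`, `n_skipped`, `skipped`).
#' @export
parse_structures <- function(path, format = c("smiles", "sdf", "pdb-het")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  out <- switch(format,
                smiles = .parse_smiles_file(path),
                sdf = .parse_sdf_file(path),
                `pdb-het` = .parse_pdb_het(path))
  ids <- vapply(out, function(m) m$id, character(1))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)]
    warning("duplicate ids made unique: ", paste(unique(dup), collapse = ", "))
    ids <- make.unique(ids, sep = "_")
    for (i in seq_along(out)) out[[i]]$id <- ids[i]
  }
  names(out) <- ids
  out
}

.with_report <- function(mols, n_read, skipped) {
  attr(mols, "report") <- list(n_read = n_read, n_skipped = length(skipped),
                               skipped = skipped)
  mols
}

.parse_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  mols <- list(); skipped <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    smi <- tok[1]
    id <- if (length(tok) > 1) tok[2] else paste0("mol", i)
    m <- tryCatch(smiles_to_mol(stats::setNames(smi, id),
                                source = basename(path))[[1]],
                  error = function(e) NULL)
    if (is.null(m) || nrow(m$atoms) == 0L) {
      warning("skipping malformed SMILES on line ", i, ": ", smi)
      skipped <- c(skipped, sprintf("line %d", i))
    } else {
      mols[[length(mols) + 1L]] <- m
    }
  }
  .with_report(mols, length(mols), skipped)
}

.parse_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends) && length(lines)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- list(); skipped <- character()
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:ends[k]]
    if (!any(nzchar(trimws(block)))) next
    tf <- tempfile(fileext = ".sdf")
    writeLines(c(block[!grepl("^\\$\\$\\$\\$", block)], "$$$$"), tf)
    m <- tryCatch({
      s <- suppressWarnings(ChemmineR::read.SDFset(tf))
      if (!ChemmineR::validSDF(s)[1]) stop("invalid SDF block")
      sdf_to_trmol(s[[1]], source = basename(path))
    }, error = function(e) NULL)
    if (is.null(m)) {
      # single-atom records are valid SDF but unrepresentable in ChemmineR
      m <- tryCatch({
        can <- ChemmineOB::convertFormat(
          "SDF", "CAN", paste(c(block[!grepl("^\\$\\$\\$\\$", block)], "$$$$",
                                ""), collapse = "\n"))
        tok <- strsplit(trimws(can), "[\t ]+")[[1]]
        if (!length(tok) || !nzchar(tok[1])) NULL else
          .single_atom_mol(tok[1],
                           if (length(tok) > 1) tok[2] else "mol",
                           basename(path))
      }, error = function(e) NULL)
    }
    unlink(tf)
    if (is.null(m)) {
      warning("skipping malformed SDF record ", k, " in ", basename(path))
      skipped <- c(skipped, sprintf("record %d", k))
    } else {
      if (m$id == "mol") m$id <- paste0("mol", k)
      mols[[length(mols) + 1L]] <- m
    }
  }
  .with_report(mols, length(mols), skipped)
}

.parse_pdb_het <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("the bio3d package is required for pdb-het parsing")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  het <- pdb$atom[pdb$atom$type == "HETATM" & pdb$atom$resid != "HOH", ,
                  drop = FALSE]
  mols <- list(); skipped <- character()
  if (!nrow(het)) return(.with_report(mols, 0L, skipped))
  key <- paste(het$resid, het$chain, het$resno, sep = "_")
  for (grp in split(seq_len(nrow(het)), key)) {
    a <- het[grp, , drop = FALSE]
    elems <- .normalize_element(a$elesy, a$elety)
    keep <- elems != "H"
    a <- a[keep, , drop = FALSE]; elems <- elems[keep]
    if (!nrow(a)) next
    id <- paste(a$resid[1], a$chain[1], a$resno[1], sep = "_")
    coords <- cbind(a$x, a$y, a$z)
    m <- tryCatch({
      bonds <- .perceive_bonds(elems, coords)
      trmol(atoms = data.frame(elem = elems, charge = 0L, nH = 0L),
            bonds = bonds, coords = coords, id = id,
            source = basename(path))
    }, error = function(e) NULL)
    if (is.null(m)) {
      warning("skipping HETATM residue ", id)
      skipped <- c(skipped, id)
    } else mols[[length(mols) + 1L]] <- m
  }
  # deterministic order by id
  mols <- mols[order(vapply(mols, function(m) m$id, character(1)))]
  .with_report(mols, length(mols), skipped)
}

.normalize_element <- function(elesy, elety) {
  e <- trimws(as.character(elesy))
  miss <- !nzchar(e) | is.na(e)
  if (any(miss)) e[miss] <- gsub("[0-9'\"]", "", trimws(elety[miss]))
  e <- substr(e, 1, 2)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
}

# single-order bonds from covalent-radius distance criterion
.perceive_bonds <- function(elems, coords) {
  n <- length(elems)
  if (n < 2) return(data.frame(a1 = integer(), a2 = integer(),
                               order = integer()))
  rc <- .elem_lookup(elems, "cov", "covalent radius")
  d <- as.matrix(stats::dist(coords))
  thr <- outer(rc, rc, `+`) + 0.45
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  data.frame(a1 = hit[, 1], a2 = hit[, 2],
             order = rep(1L, nrow(hit)))
}
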