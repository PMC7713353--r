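# 3D conformer generation.
#
# Embedding is delegated to a bundled Python helper running RDKit's ETKDGv3
# with an explicit random seed, so repeated runs with the same seed yield
# byte-identical geometries.  Hydrogens are added for the embedding and kept
# in the conformer (they carry their own radii in the shape overlay); the
# heavy-atom order of the input graph is preserved, so conformer atoms map
# positionally onto the molecular graph.

#' Construct a conformer object
#'
#' @param parent_id id of the parent molecule.
#' @param coords numeric matrix (n x 3, Angstrom), hydrogens included.
#' @param elems element symbol per atom.
#' @param n_heavy number of leading rows that are the parent's heavy atoms.
#' @param conf_id conformer label.
#' @param seed seed recorded for provenance.
#' @return An object of class `conformer`.
#' @export
conformer <- function(parent_id, coords, elems, n_heavy = nrow(coords),
                      conf_id = paste0(parent_id, "|c1"), seed = NA_integer_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elems),
            all(is.finite(coords)))
  radii <- .elem_lookup(elems, "vdw", "van der Waals radius")
  stopifnot(all(radii > 0))
  structure(list(parent_id = parent_id, conf_id = conf_id,
                 coords = coords, elems = elems, radii = radii,
                 n_heavy = as.integer(n_heavy), seed = seed),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s> %d atoms (%d heavy)\n", x$conf_id,
              nrow(x$coords), x$n_heavy))
  invisible(x)
}

.python_binary <- function() {
  p <- Sys.getenv("TRSCREEN_PYTHON", "")
  if (nzchar(p)) p else Sys.which("python")
}

.embed_script <- function() {
  system.file("python", "embed3d.py", package = "trscreen", mustWork = TRUE)
}

#' Generate 3D conformers for a batch of molecules
#'
#' @param mols list of `trmol` objects.
#' @param n maximum number of conformers per molecule.
#' @param seed integer random seed (required; embedding is deterministic
#'   under a fixed seed).
#' @return Named list (by molecule id) of lists of `conformer` objects.
#'   Molecules that fail to embed raise an error naming them.
#' @export
generate_conformers_batch <- function(mols, n = 10, seed) {
  if (missing(seed)) stop("an integer seed is required")
  if (!length(mols)) return(list())
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  writeLines(unlist(lapply(mols, write_sdf_text)), fin)
  status <- system2(.python_binary(),
                    c(.embed_script(), shQuote(fin), n, as.integer(seed),
                      shQuote(fout)),
                    stdout = NULL, stderr = NULL)
  if (status != 0 || !file.exists(fout))
    stop("conformer embedding subprocess failed")
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(fout))
  ids <- vapply(mols, function(m) m$id, character(1))
  n_heavy <- vapply(mols, n_heavy_atoms, integer(1))
  out <- stats::setNames(vector("list", length(mols)), ids)
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    title <- ChemmineR::sdfid(sdf)
    parent <- sub("\\|c[0-9]+$", "", title)
    j <- match(parent, ids)
    if (is.na(j)) next
    ab <- ChemmineR::atomblock(sdf)
    cf <- conformer(parent_id = parent,
                    coords = unname(ab[, 1:3, drop = FALSE]),
                    elems = sub("_.*$", "", rownames(ab)),
                    n_heavy = n_heavy[j], conf_id = title, seed = seed)
    out[[j]] <- c(out[[j]], list(cf))
  }
  failed <- ids[vapply(out, is.null, logical(1))]
  if (length(failed))
    stop("conformer embedding failed for: ", paste(failed, collapse = ", "))
  out
}

#' Generate 3D conformers for one molecule
#'
#' @param mol a `trmol` object.
#' @inheritParams generate_conformers_batch
#' @return A list of `conformer` objects (at least one).
#' @export
generate_conformers <- function(mol, n = 10, seed) {
  generate_conformers_batch(list(mol), n = n, seed = seed)[[1]]
}
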