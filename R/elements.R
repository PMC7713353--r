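# Embedded per-element data used throughout the package.
#
# vabc: additive atomic contributions (A^3) to the approximate van der Waals
#   molecular volume (Zhao, Abraham & Zissimos, J Org Chem 2003, 68, 7368).
# vdw:  Bondi van der Waals radii (A), used for shape Gaussians.
# cov:  covalent radii (A), used only for distance-based bond perception of
#   coordinate-only inputs (PDB HETATM blocks).
# mass: standard atomic weights (g/mol).
# valence: allowed standard valences (lowest first), for implicit-H counts.

.element_data <- local({
  d <- data.frame(
    elem = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
             "Se", "Br", "I"),
    vabc = c(7.24, 40.48, 20.58, 15.60, 14.71, 13.31, 38.79, 24.43, 24.43,
             22.45, 28.73, 26.52, 32.52),
    vdw  = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.10, 1.80, 1.80, 1.75,
             1.90, 1.85, 1.98),
    cov  = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.11, 1.07, 1.05, 1.02,
             1.20, 1.20, 1.39),
    mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974,
             32.06, 35.45, 78.971, 79.904, 126.904),
    stringsAsFactors = FALSE
  )
  rownames(d) <- d$elem
  d
})

.element_valences <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1
)

.elem_lookup <- function(elems, column, what = column) {
  v <- .element_data[elems, column]
  if (anyNA(v)) {
    bad <- unique(elems[is.na(v)])
    stop("no tabulated ", what, " for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  v
}

#' Atomic contribution table for the additive van der Waals volume
#'
#' Returns the embedded per-element atomic contributions (in cubic Angstrom)
#' used by [compute_vabc()], together with the Bondi van der Waals radii and
#' atomic masses the package uses elsewhere.
#'
#' @return A data frame with columns `elem`, `vabc`, `vdw`, `cov`, `mass`.
#' @export
element_table <- function() .element_data
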