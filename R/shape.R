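# Gaussian shape overlay with pharmacophore color features.
#
# Molecules are represented as sums of atom-centered Gaussians in the
# Grant-Pickup convention: amplitude p = 2.7, width set so each atom's
# Gaussian integrates to its hard-sphere volume.  Only first-order
# (pairwise) overlaps are summed; higher-order intersection corrections are
# omitted, which is standard for ranking applications.  Color features are
# typed points (donor, acceptor, cation, anion, hydrophobe, ring centroid)
# carrying 1.0-Angstrom Gaussians; only same-type features overlap.

.gauss_p <- 2.7
# alpha_i = kappa / r_i^2 makes the single-atom Gaussian integral equal to
# the hard-sphere volume 4/3 pi r^3
.gauss_kappa <- pi * (3 * .gauss_p / (4 * pi))^(2 / 3)

.gauss_alpha <- function(radii) .gauss_kappa / radii^2

# pairwise first-order Gaussian overlap between two atom sets
.gauss_cross <- function(xa, alpha_a, xb, alpha_b) {
  if (!nrow(xa) || !nrow(xb)) return(0)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  asum <- outer(alpha_a, alpha_b, `+`)
  aprod <- outer(alpha_a, alpha_b, `*`)
  sum(.gauss_p^2 * (pi / asum)^1.5 * exp(-aprod / asum * d2))
}

#' First-order Gaussian overlap volumes of two conformers
#'
#' @param A,B `conformer` objects.
#' @param transform optional rigid transform applied to `A`: a list with a
#'   3x3 rotation `R` and length-3 translation `t` (`x' = x R^T + t`).
#' @return Named numeric vector `c(V_AB, V_AA, V_BB)` (cubic Angstrom).
#' @export
gaussian_overlap_volume <- function(A, B, transform = NULL) {
  xa <- A$coords
  if (!is.null(transform))
    xa <- xa %*% t(transform$R) + rep(1, nrow(xa)) %o% transform$t
  aa <- .gauss_alpha(A$radii); ab <- .gauss_alpha(B$radii)
  c(V_AB = .gauss_cross(xa, aa, B$coords, ab),
    V_AA = .gauss_cross(A$coords, aa, A$coords, aa),
    V_BB = .gauss_cross(B$coords, ab, B$coords, ab))
}

# --- pharmacophore color features ----------------------------------------

.feature_types <- c("donor", "acceptor", "cation", "anion", "hydrophobe",
                    "ring")

#' Pharmacophore feature points of a molecule
#'
#' Types a molecule's heavy atoms by fixed rules equivalent to the package's
#' hydrogen-bond pattern set, and places feature Gaussians: donors and
#' acceptors on the atom, cations/anions on formally charged atoms, ring
#' features at SSSR ring centroids, hydrophobes at the centroid of each
#' connected all-carbon group.  All features carry radius 1.0 Angstrom.
#'
#' @param mol a `trmol` object.
#' @param coords heavy-atom coordinate matrix (defaults to `mol$coords`).
#' @return data frame with columns `type`, `x`, `y`, `z`, `radius`.
#' @export
feature_points <- function(mol, coords = mol$coords) {
  if (is.null(coords)) stop("3D coordinates required for feature points")
  coords <- as.matrix(coords)[seq_len(nrow(mol$atoms)), , drop = FALSE]
  at <- mol$atoms
  rs <- mol_rings(mol)
  arom_atoms <- unique(unlist(rs$rings[rs$aromatic]))
  feats <- list()
  add <- function(type, xyz) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, x = xyz[1], y = xyz[2], z = xyz[3], radius = 1.0)
  }
  is_no <- at$elem %in% c("N", "O")
  donor <- is_no & at$nH >= 1L
  pyrrole_nh <- at$elem == "N" & at$nH >= 1L &
    seq_len(nrow(at)) %in% arom_atoms
  acceptor <- (at$elem == "O") |
    (at$elem == "N" & at$charge <= 0L & !pyrrole_nh)
  for (i in which(donor)) add("donor", coords[i, ])
  for (i in which(acceptor)) add("acceptor", coords[i, ])
  for (i in which(at$charge > 0L)) add("cation", coords[i, ])
  for (i in which(at$charge < 0L)) add("anion", coords[i, ])
  for (ring in rs$rings)
    add("ring", colMeans(coords[ring, , drop = FALSE]))
  # hydrophobes: connected groups of carbons with no heteroatom neighbour
  adj <- .mol_adjacency(mol)
  pure_c <- vapply(seq_len(nrow(at)), function(i) {
    at$elem[i] == "C" && at$charge[i] == 0L &&
      all(at$elem[adj[[i]]] == "C")
  }, logical(1))
  if (any(pure_c)) {
    sub <- mol_subgraph(mol, which(pure_c))
    comps <- .mol_components(sub)
    idx <- which(pure_c)
    for (cmp in comps)
      add("hydrophobe", colMeans(coords[idx[cmp], , drop = FALSE]))
  }
  if (!length(feats))
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric()))
  do.call(rbind, feats)
}

# color overlap between two typed feature sets (same-type only)
.color_cross <- function(fa, fb) {
  if (!nrow(fa) || !nrow(fb)) return(0)
  total <- 0
  for (tp in intersect(unique(fa$type), unique(fb$type))) {
    a <- fa[fa$type == tp, , drop = FALSE]
    b <- fb[fb$type == tp, , drop = FALSE]
    total <- total + .gauss_cross(as.matrix(a[, c("x", "y", "z")]),
                                  .gauss_alpha(a$radius),
                                  as.matrix(b[, c("x", "y", "z")]),
                                  .gauss_alpha(b$radius))
  }
  total
}

# --- alignment -----------------------------------------------------------

.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.principal_axes <- function(x) {
  if (nrow(x) < 2) return(diag(3))
  e <- eigen(stats::cov(x), symmetric = TRUE)
  v <- e$vectors
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' Align a query conformer onto a reference
#'
#' Starts from centroid-superposed principal-axes alignment (all four
#' proper axis-sign flips), then refines each start by local optimization
#' of the combined shape + color overlap.  The best-scoring overlay is
#' returned.  Deterministic for fixed inputs.
#'
#' @param query,reference `conformer` objects.
#' @param query_mol,ref_mol optional `trmol` graphs used to compute color
#'   features (features are omitted when missing).
#' @param maxit iteration cap for each local refinement.
#' @return An object of class `overlay`: transform, shape volumes
#'   `V_AB`, `V_AA`, `V_BB` and color overlaps `C_AB`, `C_AA`, `C_BB`.
#' @export
align_overlay <- function(query, reference, query_mol = NULL, ref_mol = NULL,
                          maxit = 120) {
  qx <- query$coords; rx <- reference$coords
  qa <- .gauss_alpha(query$radii); ra <- .gauss_alpha(reference$radii)
  qc <- colMeans(qx); rc <- colMeans(rx)
  qx0 <- sweep(qx, 2, qc); rx0 <- sweep(rx, 2, rc)

  qf <- if (!is.null(query_mol))
    feature_points(query_mol, qx[seq_len(query$n_heavy), , drop = FALSE])
  else NULL
  rf <- if (!is.null(ref_mol))
    feature_points(ref_mol, rx[seq_len(reference$n_heavy), , drop = FALSE])
  else NULL
  qf0 <- if (!is.null(qf) && nrow(qf))
    sweep(as.matrix(qf[, c("x", "y", "z")]), 2, qc) else NULL
  rf0 <- if (!is.null(rf) && nrow(rf))
    sweep(as.matrix(rf[, c("x", "y", "z")]), 2, rc) else NULL

  color_term <- !is.null(qf0) && !is.null(rf0)
  rfl <- if (color_term) {
    f <- rf; f$x <- rf0[, 1]; f$y <- rf0[, 2]; f$z <- rf0[, 3]; f
  } else NULL

  objective <- function(par, R0) {
    R <- R0 %*% .rodrigues(par[1:3])
    xq <- qx0 %*% t(R) + rep(1, nrow(qx0)) %o% par[4:6]
    val <- .gauss_cross(xq, qa, rx0, ra)
    if (color_term) {
      fq <- qf
      fx <- qf0 %*% t(R) + rep(1, nrow(qf0)) %o% par[4:6]
      fq$x <- fx[, 1]; fq$y <- fx[, 2]; fq$z <- fx[, 3]
      val <- val + .color_cross(fq, rfl)
    }
    -val
  }

  vq <- .principal_axes(qx0); vr <- .principal_axes(rx0)
  starts <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(s) {
    d <- diag(c(s[1], s[2], s[1] * s[2]))  # proper rotations only
    vr %*% d %*% t(vq)
  })

  best <- NULL
  for (R0 in starts) {
    fit <- stats::optim(rep(0, 6), objective, R0 = R0,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) {
      best <- fit; best$R0 <- R0
    }
  }
  R <- best$R0 %*% .rodrigues(best$par[1:3])
  tvec <- best$par[4:6]

  xq <- qx0 %*% t(R) + rep(1, nrow(qx0)) %o% tvec
  V_AB <- .gauss_cross(xq, qa, rx0, ra)
  V_AA <- .gauss_cross(qx0, qa, qx0, qa)
  V_BB <- .gauss_cross(rx0, ra, rx0, ra)
  C_AB <- C_AA <- C_BB <- 0
  if (color_term) {
    fq <- qf
    fx <- qf0 %*% t(R) + rep(1, nrow(qf0)) %o% tvec
    fq$x <- fx[, 1]; fq$y <- fx[, 2]; fq$z <- fx[, 3]
    C_AB <- .color_cross(fq, rfl)
    C_AA <- .color_cross(fq, fq)
    C_BB <- .color_cross(rfl, rfl)
  } else {
    if (!is.null(qf0)) {
      fq <- qf; C_AA <- .color_cross(fq, fq)
    }
    if (!is.null(rfl)) C_BB <- .color_cross(rfl, rfl)
  }
  structure(list(query_id = query$conf_id, ref_id = reference$conf_id,
                 R = R, t = tvec, center_query = qc, center_ref = rc,
                 V_AB = V_AB, V_AA = V_AA, V_BB = V_BB,
                 C_AB = C_AB, C_AA = C_AA, C_BB = C_BB),
            class = "overlay")
}

#' @export
print.overlay <- function(x, ...) {
  cat(sprintf("<overlay %s ~ %s> V_AB=%.1f (V_AA=%.1f, V_BB=%.1f)\n",
              x$query_id, x$ref_id, x$V_AB, x$V_AA, x$V_BB))
  invisible(x)
}

#' Similarity scores of an overlay
#'
#' Shape Tanimoto `V_AB / (V_AA + V_BB - V_AB)`, the color analogue over
#' matched feature overlaps, reference-weighted Tversky variants
#' `V_AB / (alpha V_ref + (1 - alpha) V_query)`, and their combos.  Combos
#' are reported both raw (0..2) and normalized (0..1); downstream fused
#' scoring consumes the normalized values.
#'
#' @param overlay an `overlay` object.
#' @param alpha Tversky weight toward the reference (default 0.95).
#' @return An object of class `similarity_scores` (a one-row data frame).
#' @export
score_overlay <- function(overlay, alpha = 0.95) {
  with(overlay, {
    if (V_AA <= 0 || V_BB <= 0)
      stop("degenerate overlay: zero self-volume")
    # first-order cross-overlap sums can marginally exceed the smaller
    # self-overlap for strongly size-mismatched pairs; coefficients are
    # clamped to their nominal [0, 1] range
    clamp01 <- function(x) min(max(x, 0), 1)
    shape_t <- clamp01(V_AB / (V_AA + V_BB - V_AB))
    color_t <- if (C_AA > 0 && C_BB > 0)
      clamp01(C_AB / (C_AA + C_BB - C_AB)) else 0
    tv_shape <- clamp01(V_AB / (alpha * V_BB + (1 - alpha) * V_AA))
    tv_color <- if (C_AA > 0 && C_BB > 0)
      clamp01(C_AB / (alpha * C_BB + (1 - alpha) * C_AA)) else 0
    out <- data.frame(
      query_id = query_id, ref_id = ref_id,
      shape_tanimoto = shape_t, color_tanimoto = color_t,
      tanimoto_combo = shape_t + color_t,
      tanimoto_combo_norm = (shape_t + color_t) / 2,
      ref_tversky_shape = tv_shape, ref_tversky_color = tv_color,
      ref_tversky_combo = tv_shape + tv_color,
      ref_tversky_combo_norm = (tv_shape + tv_color) / 2,
      tversky_alpha = alpha)
    class(out) <- c("similarity_scores", class(out))
    out
  })
}

#' Align and score a query conformer against a reference conformer
#'
#' @inheritParams align_overlay
#' @inheritParams score_overlay
#' @return A `similarity_scores` row.
#' @export
shape_similarity <- function(query, reference, query_mol = NULL,
                             ref_mol = NULL, alpha = 0.95, maxit = 120) {
  score_overlay(align_overlay(query, reference, query_mol, ref_mol,
                              maxit = maxit), alpha = alpha)
}
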