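# The bi-directional T x R docking-score matrix: pluggable scoring,
# per-axis rank transforms, mutual-best pairs and saddle points.

#' Construct a scorer
#'
#' A scorer turns (target, ring conformers) into a docking-score-like float
#' (lower = better, kcal/mol-like), deterministically under a fixed
#' seed/configuration.  The built-in [toy_shape_scorer()] makes the
#' pipeline testable without a commercial engine; external engines plug in
#' through [command_scorer()].
#'
#' @param name scorer name.
#' @param score_fn `function(target, ring, ring_confs, ref_conf)` returning
#'   a finite numeric score or `NA` (with a `"reason"` attribute).
#' @param typed_elements elements the scorer can type; rings containing
#'   other elements are excluded from the matrix with reason
#'   `"missing atom types"`.
#' @param config configuration list passed through to adapters (search
#'   mode, box size, poses retained, ...).
#' @return An object of class `tr_scorer`.
#' @export
tr_scorer <- function(name, score_fn,
                      typed_elements = c("C", "N", "O", "F", "Cl", "Br",
                                         "I", "P", "S"),
                      config = list()) {
  structure(list(name = name, score_fn = score_fn,
                 typed_elements = typed_elements, config = config),
            class = "tr_scorer")
}

#' Built-in toy docking scorer
#'
#' Scores a ring against a target as the negative shape/color Tanimoto
#' combo complementarity of the ring to the target's reference co-crystal
#' ligand, scaled to a kcal/mol-like range.  This is a documented stand-in
#' for an external docking engine, sufficient to exercise the matrix
#' analytics; it preserves the "lower = better" convention.
#'
#' @param scale multiplier from normalized combo (0..1) to the score range
#'   (default -12, so a perfect shape match scores -12 kcal/mol-like units).
#' @param maxit overlay refinement iterations per conformer pair.
#' @param config passed through as scorer configuration (e.g. the 10 A
#'   docking box schema for external adapters).
#' @return A `tr_scorer`.
#' @export
toy_shape_scorer <- function(scale = -12, maxit = 60, config = list()) {
  tr_scorer(
    name = "toy_shape",
    score_fn = function(target, ring, ring_confs, ref) {
      best <- 0
      for (qc in ring_confs) {
        s <- shape_similarity(qc, ref$conf, ring$mol, ref$mol, maxit = maxit)
        best <- max(best, s$tanimoto_combo_norm)
      }
      scale * best
    },
    config = config)
}

#' External docking engine adapter
#'
#' Wraps a command-line engine under the subprocess contract: the command
#' is called as `cmd <receptor_file> <ligand_sdf>` and must print a single
#' numeric score to stdout.
#'
#' @param cmd path to the engine executable or wrapper script.
#' @param config engine configuration (e.g. search mode `"SP"`/`"XP"`,
#'   `box = c(10, 10, 10)`, vdW scaling, poses retained) recorded and
#'   passed through.
#' @return A `tr_scorer`.
#' @export
command_scorer <- function(cmd, config = list(mode = "SP",
                                              box = c(10, 10, 10),
                                              vdw_scaling = 1.0,
                                              charge_cutoff = 0.25,
                                              postdock_min = 0.5,
                                              poses = 10)) {
  tr_scorer(
    name = paste0("cmd:", basename(cmd)),
    score_fn = function(target, ring, ring_confs, ref) {
      lig <- tempfile(fileext = ".sdf")
      on.exit(unlink(lig))
      writeLines(unlist(lapply(ring_confs, function(cf) {
        write_sdf_text(ring$mol, coords = cf$coords[seq_len(cf$n_heavy), ,
                                                    drop = FALSE])
      })), lig)
      out <- tryCatch(
        system2(cmd, c(shQuote(ref$receptor_file %||% ""), shQuote(lig)),
                stdout = TRUE, stderr = FALSE),
        error = function(e) NA_character_)
      val <- suppressWarnings(as.numeric(out[1]))
      if (!is.finite(val)) {
        val <- NA_real_
        attr(val, "reason") <- "engine failure"
      }
      val
    },
    config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score every (target, ring) cell of the TR matrix
#'
#' Runs the scorer on each ring against each PDB reference ligand of each
#' target, then merges per-PDB scores to one score per target (best, i.e.
#' most negative, by default; `merge = "mean"` available).  Rings the
#' scorer cannot type are excluded with reason `"missing atom types"`;
#' scorer failures leave missing cells with a logged reason, never a crash.
#'
#' @param rings list of `ring_system` objects.
#' @param targets list of `target_record` objects; each target's co-crystal
#'   ligands serve as its per-PDB references.
#' @param scorer a `tr_scorer` (default [toy_shape_scorer()]).
#' @param seed integer seed for conformer embedding.
#' @param n_confs conformers per ring (default 2; the screened ring systems
#'   are rigid fused assemblies).
#' @param merge `"best"` or `"mean"` across a target's PDBs.
#' @return An object of class `score_matrix`: `scores` (targets x rings),
#'   `excluded_rings`, `failures`.
#' @export
dock_all <- function(rings, targets, scorer = toy_shape_scorer(), seed,
                     n_confs = 2, merge = c("best", "mean")) {
  merge <- match.arg(merge)
  if (missing(seed)) stop("an integer seed is required")
  ring_ids <- vapply(rings, function(r) r$ring_id, character(1))
  target_ids <- vapply(targets, function(t) t$uniprot, character(1))

  typed <- vapply(rings, function(r)
    all(r$mol$atoms$elem %in% scorer$typed_elements), logical(1))
  excluded <- data.frame(ring_id = ring_ids[!typed],
                         reason = rep("missing atom types", sum(!typed)))
  rings_in <- rings[typed]
  ring_ids_in <- ring_ids[typed]

  ring_confs <- generate_conformers_batch(
    lapply(rings_in, function(r) r$mol), n = n_confs, seed = seed)
  ref_mols <- list(); ref_of <- list()
  for (i in seq_along(targets)) {
    ligs <- targets[[i]]$ligands
    for (j in seq_along(ligs)) {
      key <- paste0(target_ids[i], "#", j)
      l <- ligs[[j]]; l$id <- key
      ref_mols[[key]] <- l
      ref_of[[key]] <- i
    }
  }
  ref_confs <- if (length(ref_mols))
    generate_conformers_batch(ref_mols, n = 1, seed = seed + 1L) else list()

  scores <- matrix(NA_real_, nrow = length(targets), ncol = length(rings_in),
                   dimnames = list(target_ids, ring_ids_in))
  counts <- matrix(0L, length(targets), length(rings_in))
  failures <- list()
  for (ci in seq_along(rings_in)) {
    ring <- rings_in[[ci]]
    for (key in names(ref_mols)) {
      ti <- ref_of[[key]]
      ref <- list(conf = ref_confs[[key]][[1]], mol = ref_mols[[key]],
                  receptor_file = targets[[ti]]$receptor_file %||% NULL)
      val <- tryCatch(
        scorer$score_fn(targets[[ti]], ring, ring_confs[[ci]], ref),
        error = function(e) {
          v <- NA_real_; attr(v, "reason") <- conditionMessage(e); v
        })
      if (is.na(val)) {
        failures[[length(failures) + 1L]] <- data.frame(
          target_id = target_ids[ti], ring_id = ring$ring_id, pdb = key,
          reason = attr(val, "reason") %||% "scorer failure")
        next
      }
      cur <- scores[ti, ci]
      scores[ti, ci] <- if (is.na(cur)) val else
        if (merge == "best") min(cur, val) else cur + val
      counts[ti, ci] <- counts[ti, ci] + 1L
    }
  }
  if (merge == "mean")
    scores[] <- ifelse(counts > 0, scores / counts, NA_real_)
  structure(list(scores = scores, target_ids = target_ids,
                 ring_ids = ring_ids_in, excluded_rings = excluded,
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL,
                 scorer = scorer$name),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d targets x %d rings (%d excluded)\n",
              nrow(x$scores), ncol(x$scores), nrow(x$excluded_rings)))
  invisible(x)
}

# rank one vector: 1 = most negative; ties broken by id order (ordinal)
.rank_vector <- function(v, ids) {
  out <- rep(NA_integer_, length(v))
  ok <- which(!is.na(v))
  if (!length(ok)) return(out)
  ord <- ok[order(v[ok], ids[ok])]
  out[ord] <- seq_along(ord)
  out
}

#' Rank-transform a score matrix along one axis
#'
#' Rank 1 is the most negative (best) score.  Ties are broken
#' deterministically by id; missing cells stay unranked; an all-missing
#' vector is flagged rather than ranked.
#'
#' @param m a `score_matrix` (or bare numeric matrix with dimnames).
#' @param axis `"rows"` ranks within each row (ranking rings for each
#'   target); `"columns"` ranks within each column (ranking targets for
#'   each ring).
#' @return An integer matrix of class `rank_matrix` with attributes `axis`
#'   and `unranked` (ids of all-missing vectors).
#' @export
rank_transform <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  scores <- if (inherits(m, "score_matrix")) m$scores else m
  ranks <- matrix(NA_integer_, nrow(scores), ncol(scores),
                  dimnames = dimnames(scores))
  unranked <- character()
  if (axis == "rows") {
    for (i in seq_len(nrow(scores))) {
      if (all(is.na(scores[i, ]))) {
        unranked <- c(unranked, rownames(scores)[i]); next
      }
      ranks[i, ] <- .rank_vector(scores[i, ], colnames(scores))
    }
  } else {
    for (j in seq_len(ncol(scores))) {
      if (all(is.na(scores[, j]))) {
        unranked <- c(unranked, colnames(scores)[j]); next
      }
      ranks[, j] <- .rank_vector(scores[, j], rownames(scores))
    }
  }
  structure(ranks, axis = axis, unranked = unranked,
            class = c("rank_matrix", "matrix", "array"))
}

#' Mutual-best (target, ring) pairs
#'
#' Returns the cells ranked 1 along both axes; may be empty.
#'
#' @param row_ranks rank matrix from `rank_transform(m, "rows")`.
#' @param col_ranks rank matrix from `rank_transform(m, "columns")`.
#' @param scores optional score matrix to annotate the pairs.
#' @return data frame: target_id, ring_id, score, rank_in_ring_axis (within
#'   the target's row), rank_in_target_axis (within the ring's column),
#'   mutual_best.
#' @export
mutual_best_pairs <- function(row_ranks, col_ranks, scores = NULL) {
  stopifnot(all(dim(row_ranks) == dim(col_ranks)))
  hit <- which(row_ranks == 1L & col_ranks == 1L, arr.ind = TRUE)
  out <- data.frame(target_id = rownames(row_ranks)[hit[, 1]],
                    ring_id = colnames(row_ranks)[hit[, 2]],
                    score = if (is.null(scores)) NA_real_ else scores[hit],
                    rank_in_ring_axis = 1L, rank_in_target_axis = 1L,
                    mutual_best = TRUE)
  out[order(out$target_id, out$ring_id), , drop = FALSE]
}

#' Saddle-point cells of the rank matrices
#'
#' Flags cells that are best (rank at most `good_rank`) along one axis but
#' fall in the worst `bad_quantile` of the other axis — the minimax trap
#' bi-directional screening is designed to expose.  The saddle index is
#' `(rank_other - 1) / (k - 1)`, 0 for a mutual best and 1 for the very
#' worst opposite rank.
#'
#' @inheritParams mutual_best_pairs
#' @param good_rank rank threshold on the good axis (default 1).
#' @param bad_quantile fraction defining "the worst" of the other axis
#'   (default 0.5).
#' @return data frame: target_id, ring_id, good_axis, rank_good,
#'   rank_other, saddle_index.
#' @export
saddle_points <- function(row_ranks, col_ranks, good_rank = 1,
                          bad_quantile = 0.5, scores = NULL) {
  stopifnot(all(dim(row_ranks) == dim(col_ranks)))
  res <- list()
  nr <- nrow(row_ranks); nc <- ncol(row_ranks)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- row_ranks[i, j]; cr <- col_ranks[i, j]
    if (is.na(rr) || is.na(cr)) next
    k_row <- sum(!is.na(row_ranks[i, ]))   # rings ranked in this row
    k_col <- sum(!is.na(col_ranks[, j]))   # targets ranked in this column
    # best ring for the target, but poorly ranked target for the ring
    if (rr <= good_rank && k_col > 1 && cr > k_col * (1 - bad_quantile)) {
      res[[length(res) + 1L]] <- data.frame(
        target_id = rownames(row_ranks)[i], ring_id = colnames(row_ranks)[j],
        good_axis = "ring_for_target", rank_good = rr, rank_other = cr,
        saddle_index = (cr - 1) / (k_col - 1))
    }
    # best target for the ring, but poorly ranked ring for the target
    if (cr <= good_rank && k_row > 1 && rr > k_row * (1 - bad_quantile)) {
      res[[length(res) + 1L]] <- data.frame(
        target_id = rownames(row_ranks)[i], ring_id = colnames(row_ranks)[j],
        good_axis = "target_for_ring", rank_good = cr, rank_other = rr,
        saddle_index = (rr - 1) / (k_row - 1))
    }
  }
  if (!length(res))
    return(data.frame(target_id = character(), ring_id = character(),
                      good_axis = character(), rank_good = integer(),
                      rank_other = integer(), saddle_index = numeric()))
  out <- do.call(rbind, res)
  out[order(out$target_id, out$ring_id, out$good_axis), , drop = FALSE]
}

#' Export a rank matrix as CSV and heatmap image
#'
#' Writes the rank grid as CSV (byte-identical on re-export) and renders a
#' heatmap with the best ranks dark blue and the worst yellow.
#'
#' @param rank_matrix a `rank_matrix`.
#' @param path output path without extension (`.csv` and `.png` appended).
#' @param main plot title.
#' @return Invisibly, the paths written.
#' @export
export_heatmap <- function(rank_matrix, path, main = "TR rank matrix") {
  csv <- paste0(path, ".csv"); png_path <- paste0(path, ".png")
  m <- unclass(rank_matrix)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  utils::write.csv(as.data.frame(m), csv, row.names = TRUE)
  pal <- grDevices::colorRampPalette(
    c("#00008B", "#2E5FA8", "#7FB2D0", "#D9E8A0", "#FFFF00"))(100)
  grDevices::png(png_path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  col = pal, xlab = "ring", ylab = "target", main = main,
                  axes = FALSE)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.6)
  invisible(c(csv = csv, png = png_path))
}
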