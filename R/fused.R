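# Per-pair similarity statistics and the multiplicative fused score.
#
# For one ring system against one target's retained co-crystal ligand
# overlays, the retained comparisons (pooled over ligands and conformers)
# are reduced to max/mean/min statistics per metric family, and the fused
# score is their product:
#
#   fused = RefTverskyCombo_Max * TanimotoCombo_Mean * RefTverskyCombo_Mean
#           * TanimotoCombo_Max * RefTverskyCombo_Min * ColorTanimoto_Min
#           * count
#
# Multiplication is deliberately more sensitive to variance between the
# factors than summation, and annihilates a pair as soon as any factor is
# zero.  All metrics enter on the normalized [0, 1] scale.

#' Aggregate similarity scores for one (ring, target) pair
#'
#' Retains scores with normalized Tanimoto combo above `cutoff`, caps the
#' retained set at `max_results` by descending Tanimoto combo, and computes
#' the per-metric statistics the fused score consumes.  A pair with no
#' retained comparison is marked unscored (distinct from a fused score of
#' zero).
#'
#' @param scores data frame of `similarity_scores` rows (one per retained
#'   ligand-conformer overlay).
#' @param ring_id,target_id pair identifiers.
#' @param cutoff retention cutoff on the normalized Tanimoto combo
#'   (default -0.1, i.e. low-scoring results are kept too).
#' @param max_results cap on retained comparisons (default 500).
#' @return An object of class `pair_statistics`, or `NULL` when the pair is
#'   unscored.
#' @export
aggregate_pair <- function(scores, ring_id = "ring", target_id = "target",
                           cutoff = -0.1, max_results = 500) {
  if (is.null(scores) || !nrow(scores)) return(NULL)
  keep <- scores$tanimoto_combo_norm > cutoff
  scores <- scores[keep, , drop = FALSE]
  if (!nrow(scores)) return(NULL)
  ord <- order(-scores$tanimoto_combo_norm)
  scores <- scores[ord[seq_len(min(nrow(scores), max_results))], ,
                   drop = FALSE]
  out <- data.frame(
    ring_id = ring_id, target_id = target_id,
    ref_tversky_combo_max = max(scores$ref_tversky_combo_norm),
    tanimoto_combo_mean = mean(scores$tanimoto_combo_norm),
    ref_tversky_combo_mean = mean(scores$ref_tversky_combo_norm),
    tanimoto_combo_max = max(scores$tanimoto_combo_norm),
    ref_tversky_combo_min = min(scores$ref_tversky_combo_norm),
    color_tanimoto_min = min(scores$color_tanimoto),
    count = nrow(scores))
  class(out) <- c("pair_statistics", class(out))
  out
}

#' Multiplicative fused score of a pair's statistics
#'
#' @param stats a `pair_statistics` row.
#' @return An object of class `fused_score`: list with `value` and the
#'   seven `components`.
#' @export
fused_score <- function(stats) {
  comp <- c(ref_tversky_combo_max = stats$ref_tversky_combo_max,
            tanimoto_combo_mean = stats$tanimoto_combo_mean,
            ref_tversky_combo_mean = stats$ref_tversky_combo_mean,
            tanimoto_combo_max = stats$tanimoto_combo_max,
            ref_tversky_combo_min = stats$ref_tversky_combo_min,
            color_tanimoto_min = stats$color_tanimoto_min,
            count = stats$count)
  structure(list(value = prod(comp), components = comp),
            class = "fused_score")
}

#' @export
print.fused_score <- function(x, ...) {
  cat(sprintf("<fused_score %.4g> (count %d)\n", x$value,
              as.integer(x$components[["count"]])))
  invisible(x)
}

#' Best target per ring and best ring per target
#'
#' Argmax of the fused score along each axis of the pair table.  Ties are
#' broken by lexicographic id; unscored pairs never win.  An axis entry
#' whose every pair is unscored is flagged `"no similar ring"` /
#' `"no similar target"` rather than assigned.
#'
#' @param pairs data frame with columns `ring_id`, `target_id`, `fused`
#'   (`NA` for unscored pairs).
#' @return list with data frames `best_target_per_ring` (ring_id,
#'   target_id, fused, flag) and `best_ring_per_target`.
#' @export
best_lists <- function(pairs) {
  pick <- function(group_col, other_col, flag_label) {
    groups <- sort(unique(pairs[[group_col]]))
    do.call(rbind, lapply(groups, function(g) {
      sub <- pairs[pairs[[group_col]] == g, , drop = FALSE]
      sub <- sub[!is.na(sub$fused), , drop = FALSE]
      if (!nrow(sub))
        return(stats::setNames(
          data.frame(g, NA_character_, NA_real_, flag_label,
                     stringsAsFactors = FALSE),
          c(group_col, other_col, "fused", "flag")))
      sub <- sub[order(-sub$fused, sub[[other_col]]), , drop = FALSE]
      stats::setNames(
        data.frame(g, sub[[other_col]][1], sub$fused[1], NA_character_,
                   stringsAsFactors = FALSE),
        c(group_col, other_col, "fused", "flag"))
    }))
  }
  list(best_target_per_ring = pick("ring_id", "target_id",
                                   "no similar target"),
       best_ring_per_target = pick("target_id", "ring_id",
                                   "no similar ring"))
}

#' Score every (ring, target) pair of a shape screen
#'
#' Convenience wrapper: aggregates each pair's retained overlays and
#' attaches the fused score.
#'
#' @param score_table data frame of similarity scores with `ring_id` and
#'   `target_id` columns.
#' @param cutoff,max_results passed to [aggregate_pair()].
#' @return data frame: one row per pair with the seven factors and `fused`
#'   (`NA` marks unscored pairs).
#' @export
fuse_pairs <- function(score_table, cutoff = -0.1, max_results = 500) {
  combos <- unique(score_table[, c("ring_id", "target_id")])
  combos <- combos[order(combos$ring_id, combos$target_id), , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    r <- combos$ring_id[k]; t <- combos$target_id[k]
    sub <- score_table[score_table$ring_id == r &
                         score_table$target_id == t, , drop = FALSE]
    st <- aggregate_pair(sub, r, t, cutoff = cutoff,
                         max_results = max_results)
    if (is.null(st))
      return(data.frame(ring_id = r, target_id = t,
                        ref_tversky_combo_max = NA_real_,
                        tanimoto_combo_mean = NA_real_,
                        ref_tversky_combo_mean = NA_real_,
                        tanimoto_combo_max = NA_real_,
                        ref_tversky_combo_min = NA_real_,
                        color_tanimoto_min = NA_real_,
                        count = NA_integer_, fused = NA_real_))
    st$fused <- fused_score(st)$value
    class(st) <- "data.frame"
    st
  }))
}
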