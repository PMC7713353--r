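# End-to-end pipeline: fixtures/inputs -> ring filter -> target filter ->
# shape screen -> fused scores -> best lists -> TR matrix -> ranks ->
# mutual-best / saddle analysis -> optional library enumeration.
#
# Every stage writes its artifact under the run directory; re-running with
# the same config and seed reproduces all CSVs byte-identically.  A
# manifest lists every file with its checksum.

#' Default run configuration
#'
#' @param seed integer seed used for every stochastic step.
#' @param out_dir run directory.
#' @param fixtures `fixture_spec` arguments (list) used when no explicit
#'   inputs are given.
#' @param inputs optional list of file paths (`rings_smi`, `rings_csv`,
#'   `targets_csv`, `ligands_smi`, `reagents_smi`) read instead of
#'   generating fixtures.
#' @param ring_filter,target_filter,shape,saddle,enumeration stage settings.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("trscreen_run_"),
                       fixtures = list(), inputs = NULL,
                       ring_filter = list(vabc_min = 140,
                                          hahb_max_exclusive = 3,
                                          freq_max_exclusive = 3),
                       target_filter = list(),
                       shape = list(n_confs = 2, cutoff = -0.1,
                                    max_results = 500, tversky_alpha = 0.95,
                                    maxit = 60),
                       saddle = list(good_rank = 1, bad_quantile = 0.5),
                       enumeration = list(enabled = TRUE, ro5_max = 2,
                                          ro3_max = 1)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 fixtures = fixtures, inputs = inputs,
                 ring_filter = ring_filter, target_filter = target_filter,
                 shape = shape, saddle = saddle,
                 enumeration = enumeration),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- run_config()
  for (k in intersect(names(y), names(base))) {
    if (is.list(base[[k]]) && is.list(y[[k]]))
      base[[k]] <- utils::modifyList(base[[k]], y[[k]])
    else base[[k]] <- y[[k]]
  }
  if (!is.null(y$seed)) base$seed <- as.integer(y$seed)
  base
}

.stage_log <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full bi-directional TR screening pipeline
#'
#' @param config a `run_config` (or YAML path).
#' @return Invisibly, a list with the run directory, the planted truths (if
#'   fixtures were generated), the stage artifacts and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- character()

  # --- stage 0: inputs ----------------------------------------------------
  if (is.null(config$inputs)) {
    spec <- do.call(fixture_spec,
                    utils::modifyList(list(seed = config$seed),
                                      config$fixtures))
    fixdir <- file.path(out, "fixtures")
    paths <- write_fixture_files(spec, fixdir)
    log <- .stage_log(log, "fixtures", sprintf(
      "generated (seed %d)", config$seed))
  } else {
    paths <- config$inputs
    for (p in unlist(paths)) if (!is.null(p) && !file.exists(p))
      stop("missing input path: ", p)
  }

  ring_mols <- parse_structures(paths$rings_smi, "smiles")
  ring_tab <- utils::read.csv(paths$rings_csv, stringsAsFactors = FALSE)
  rings <- lapply(ring_mols, function(m) {
    fr <- ring_tab$frequency[match(m$id, ring_tab$id)]
    ring_system(m, ring_id = m$id, frequency = fr)
  })
  targets <- read_target_table(paths$targets_csv, paths$ligands_smi)
  log <- .stage_log(log, "inputs", sprintf(
    "%d ring systems, %d targets", length(rings), length(targets)))

  # --- stage 1: ring filter ----------------------------------------------
  rf <- do.call(filter_ring_systems,
                c(list(rings = rings), config$ring_filter))
  fs <- funnel_summary(rf$funnel)
  utils::write.csv(fs, file.path(out, "ring_funnel.csv"), row.names = FALSE)
  write_descriptor_table(rf$kept, rf$descriptors,
                         file.path(out, "rings_kept.csv"))
  log <- .stage_log(log, "ring_filter", paste(
    c(fs$n_in[1], fs$n_out), collapse = " -> "))

  # --- stage 2: target filter --------------------------------------------
  tf <- do.call(filter_targets,
                c(list(targets = targets), config$target_filter))
  fs2 <- funnel_summary(tf$funnel)
  utils::write.csv(fs2, file.path(out, "target_funnel.csv"),
                   row.names = FALSE)
  log <- .stage_log(log, "target_filter", paste(
    c(fs2$n_in[1], fs2$n_out), collapse = " -> "))
  if (!length(rf$kept) || !length(tf$kept))
    stop("pipeline halted at filtering: nothing left to screen")

  # --- stage 3: co-crystal ligand pool -----------------------------------
  ligands <- list(); lig_target <- character(); lig_label <- character()
  for (t in tf$kept) for (l in t$ligands) {
    ligands[[length(ligands) + 1L]] <- l
    lig_target <- c(lig_target, t$uniprot)
    lig_label <- c(lig_label, t$development_label)
  }
  lp <- filter_pdb_ligands(ligands, lig_label)
  keep_idx <- which(lp$report$items$pass)
  log <- .stage_log(log, "pdb_ligands", sprintf(
    "%d -> %d", lp$report$n_in, lp$report$n_out))

  # --- stage 4: shape screen ---------------------------------------------
  shp <- config$shape
  ring_confs <- generate_conformers_batch(
    lapply(rf$kept, function(r) r$mol), n = shp$n_confs,
    seed = config$seed)
  lig_confs <- generate_conformers_batch(
    lp$kept, n = 1, seed = config$seed + 1L)
  rows <- list()
  for (ri in seq_along(rf$kept)) {
    ring <- rf$kept[[ri]]
    for (li in seq_along(lp$kept)) {
      ref_mol <- lp$kept[[li]]
      for (qc in ring_confs[[ri]]) {
        s <- shape_similarity(qc, lig_confs[[li]][[1]], ring$mol, ref_mol,
                              alpha = shp$tversky_alpha, maxit = shp$maxit)
        s$ring_id <- ring$ring_id
        s$target_id <- lig_target[keep_idx[li]]
        rows[[length(rows) + 1L]] <- s
      }
    }
  }
  score_table <- do.call(rbind, lapply(rows, function(r) {
    class(r) <- "data.frame"; r
  }))
  utils::write.csv(score_table, file.path(out, "shape_scores.csv"),
                   row.names = FALSE)
  log <- .stage_log(log, "shape_screen", sprintf(
    "%d comparisons", nrow(score_table)))

  # --- stage 5: fused scores and best lists ------------------------------
  pairs <- fuse_pairs(score_table, cutoff = shp$cutoff,
                      max_results = shp$max_results)
  utils::write.csv(pairs, file.path(out, "fused_scores.csv"),
                   row.names = FALSE)
  bl <- best_lists(pairs)
  utils::write.csv(bl$best_target_per_ring,
                   file.path(out, "best_target_per_ring.csv"),
                   row.names = FALSE)
  utils::write.csv(bl$best_ring_per_target,
                   file.path(out, "best_ring_per_target.csv"),
                   row.names = FALSE)
  log <- .stage_log(log, "fused", sprintf("%d pairs scored", nrow(pairs)))

  # --- stage 6: docking matrix and bi-directional ranks ------------------
  sm <- dock_all(rf$kept, tf$kept, toy_shape_scorer(maxit = shp$maxit),
                 seed = config$seed + 2L, n_confs = shp$n_confs)
  utils::write.csv(as.data.frame(sm$scores),
                   file.path(out, "score_matrix.csv"), row.names = TRUE)
  if (nrow(sm$excluded_rings))
    utils::write.csv(sm$excluded_rings,
                     file.path(out, "excluded_rings.csv"),
                     row.names = FALSE)
  rr <- rank_transform(sm, "rows")
  cr <- rank_transform(sm, "columns")
  export_heatmap(rr, file.path(out, "ranks_rows"),
                 main = "ring ranks within each target")
  export_heatmap(cr, file.path(out, "ranks_columns"),
                 main = "target ranks within each ring")
  mb <- mutual_best_pairs(rr, cr, sm$scores)
  sp <- do.call(saddle_points,
                c(list(row_ranks = rr, col_ranks = cr), config$saddle))
  utils::write.csv(mb, file.path(out, "mutual_best_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(sp, file.path(out, "saddle_points.csv"),
                   row.names = FALSE)
  log <- .stage_log(log, "tr_matrix", sprintf(
    "%d x %d matrix, %d excluded ring(s), %d mutual-best, %d saddle",
    nrow(sm$scores), ncol(sm$scores), nrow(sm$excluded_rings), nrow(mb),
    nrow(sp)))

  # --- stage 7: optional library enumeration -----------------------------
  products <- NULL
  if (isTRUE(config$enumeration$enabled) && nrow(mb)) {
    best_ring_id <- mb$ring_id[1]
    core_mol <- rf$kept[[match(best_ring_id,
                               vapply(rf$kept, function(r) r$ring_id,
                                      character(1)))]]$mol
    n_idx <- which(core_mol$atoms$elem == "N" & core_mol$atoms$nH >= 1L)
    if (length(n_idx)) {
      core <- core_scaffold(core_mol, n_idx[1],
                            note = paste("best ring", best_ring_id))
      reagents <- lapply(parse_structures(paths$reagents_smi, "smiles"),
                         function(m) tryCatch(reagent_record(m),
                                              error = function(e) m))
      products <- enumerate_n_arylation(core, reagents)
      dl <- druglikeness_filter(products,
                                ro5_max = config$enumeration$ro5_max,
                                ro3_max = config$enumeration$ro3_max)
      ptab <- do.call(rbind, lapply(products, function(p) data.frame(
        id = p$mol$id, formula = mol_formula_string(p$mol),
        heavy_atoms = p$heavy_atom_count, mw = p$mw, logp = p$logp,
        psa = p$psa, rotatable_bonds = p$rotatable_bonds,
        ro5_violations = p$ro5_violations,
        ro3_violations = p$ro3_violations,
        pains_pass = p$pains_pass, protonated_amide = p$protonated_amide,
        druglike = p$mol$id %in% vapply(dl$kept, function(q) q$mol$id,
                                        character(1)))))
      utils::write.csv(ptab, file.path(out, "library.csv"),
                       row.names = FALSE)
      log <- .stage_log(log, "enumeration", sprintf(
        "%d products (%d drug-like) grown on %s",
        length(products), length(dl$kept), best_ring_id))
    }
  }

  # --- manifest -----------------------------------------------------------
  writeLines(log, file.path(out, "run.log"))
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                   file.path(out, "config.yaml"))
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)

  invisible(list(out_dir = out,
                 planted = if (is.null(config$inputs))
                   jsonlite::read_json(paths$planted_json) else NULL,
                 rings_kept = rf$kept, targets_kept = tf$kept,
                 score_table = score_table, pairs = pairs,
                 best_lists = bl, score_matrix = sm,
                 row_ranks = rr, col_ranks = cr,
                 mutual_best = mb, saddles = sp,
                 products = products, manifest = manifest))
}
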