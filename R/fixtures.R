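# Synthetic fixtures: deterministic generation of every input the pipeline
# needs (ring tables, target metadata with toy co-crystal ligands, reagent
# sets), with planted ground truths the downstream stages must recover.
#
# Fixtures use real, valenced chemistry drawn from an embedded vocabulary
# of genuine fused-ring scaffolds and drug-like ligands, so descriptor and
# SMARTS code paths are exercised for real.  They make no claim to
# statistical realism of approved-drug chemistry space.

#' Fixture specification
#'
#' @param seed integer seed; identical specs produce identical fixtures.
#' @param n_rings total ring systems in the table.
#' @param n_pass_freq how many survive the frequency stage.
#' @param n_pass_vabc how many of those survive the volume stage.
#' @param n_pass_hahb how many of those survive the H-bond stage (the final
#'   screened set; must be at least 3 when a mutual best is planted, since
#'   the planted ring, an elongated ring and an untypeable ring are all
#'   drawn from this set).
#' @param n_targets total targets; `n_pass_targets` survive the target
#'   funnel.
#' @param n_reagents reagents in the set (the first eight are the
#'   benchmark substituent patterns; extras are simple aryl bromides).
#' @param n_untypeable rings (among the final survivors) containing an
#'   element the built-in scorer cannot type (selenium), excluded at the
#'   docking stage.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_rings = 12L, n_pass_freq = 10L,
                         n_pass_vabc = 7L, n_pass_hahb = 5L,
                         n_targets = 8L, n_pass_targets = 5L,
                         n_reagents = 10L, n_untypeable = 1L) {
  stopifnot(n_rings >= n_pass_freq, n_pass_freq >= n_pass_vabc,
            n_pass_vabc >= n_pass_hahb, n_pass_hahb >= 1L,
            n_targets >= n_pass_targets, n_pass_targets >= 2L,
            n_untypeable < n_pass_hahb)
  structure(list(seed = as.integer(seed), n_rings = as.integer(n_rings),
                 n_pass_freq = as.integer(n_pass_freq),
                 n_pass_vabc = as.integer(n_pass_vabc),
                 n_pass_hahb = as.integer(n_pass_hahb),
                 n_targets = as.integer(n_targets),
                 n_pass_targets = as.integer(n_pass_targets),
                 n_reagents = as.integer(n_reagents),
                 n_untypeable = as.integer(n_untypeable)),
            class = "fixture_spec")
}

# run fn with a private RNG stream
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# ring-system vocabulary; pass/fail character is computed, not asserted
.ring_vocab <- list(
  # large, low-polarity fused assemblies (survive volume and H-bond stages)
  survivors = c(
    cyproheptadine = "C1CC(=C2c3ccccc3C=Cc3ccccc32)CCN1",
    anthracene = "c1ccc2cc3ccccc3cc2c1",
    phenanthrene = "c1ccc2c(c1)ccc1ccccc21",
    pyrene = "c1cc2ccc3cccc4ccc(c1)c2c34",
    fluorene = "C1c2ccccc2-c2ccccc21",
    dibenzosuberene = "C1c2ccccc2C=Cc2ccccc21",
    triphenylene = "c1ccc2c(c1)c1ccccc1c1ccccc21",
    acridine = "c1ccc2nc3ccccc3cc2c1",
    chrysene = "c1ccc2c(c1)ccc1c2ccc2ccccc21"),
  # selenium-containing survivors the toy scorer cannot type
  untypeable = c(
    dibenzoselenophene = "c1ccc2c(c1)[se]c1ccccc12",
    selenanthrene = "c1ccc2c(c1)[se]c1ccccc1[se]2"),
  # large but polar (fail the H-bond stage)
  polar = c(
    phendione = "O=C1C(=O)c2cccnc2-c2ncccc21",
    diazaanthraquinone = "O=C1c2ccccc2C(=O)c2ncncc21",
    alloxazine = "O=C1NC(=O)c2nc3ccccc3nc2N1"),
  # smaller than the volume cutoff
  small = c(
    benzene = "c1ccccc1",
    naphthalene = "c1ccc2ccccc2c1",
    indole = "c1ccc2[nH]ccc2c1",
    quinoline = "c1ccc2ncccc2c1",
    cyclohexane = "C1CCCCC1",
    benzofuran = "c1ccc2occc2c1")
)

#' Generate a synthetic ring table
#'
#' Draws ring systems from the embedded scaffold vocabulary and assigns
#' drug frequencies so that exactly the planted numbers survive each filter
#' stage of [filter_ring_systems()].  The planted best ring (the
#' cyproheptadine assembly) and the untypeable selenium rings are always
#' among the final survivors.
#'
#' @param spec a `fixture_spec`.
#' @return list with `rings` (ring_system list), `descriptors` (parallel
#'   descriptor list) and `planted` (ids per category).
#' @export
make_ring_table <- function(spec) {
  if (spec$n_rings == 0L)
    return(list(rings = list(), descriptors = list(),
                planted = list()))
  .with_seed(spec$seed, function() {
    v <- .ring_vocab
    n_surv <- spec$n_pass_hahb
    n_polar <- spec$n_pass_vabc - spec$n_pass_hahb
    n_small <- spec$n_pass_freq - spec$n_pass_vabc
    n_freq_fail <- spec$n_rings - spec$n_pass_freq
    if (n_surv - spec$n_untypeable > length(v$survivors) + 1 ||
        spec$n_untypeable > length(v$untypeable) ||
        n_polar > length(v$polar))
      stop("infeasible plant: vocabulary too small for requested counts")
    surv <- c(v$survivors[c("cyproheptadine", "anthracene")],
              if (spec$n_untypeable > 0)
                v$untypeable[seq_len(spec$n_untypeable)],
              v$survivors[setdiff(names(v$survivors),
                                  c("cyproheptadine", "anthracene"))])
    surv <- surv[seq_len(n_surv)]
    polar <- v$polar[seq_len(n_polar)]
    small_pool <- rep(v$small, length.out = max(n_small, 1L))
    small <- if (n_small > 0) small_pool[seq_len(n_small)] else character()
    # frequency-stage failures drawn from any category, frequency >= 3
    pool <- c(v$survivors, v$polar, v$small)
    fails <- if (n_freq_fail > 0)
      pool[1L + (seq_len(n_freq_fail) - 1L) %% length(pool)] else character()
    smiles <- c(surv, polar, small, fails)
    freq <- c(sample(0:2, length(surv) + length(polar) + length(small),
                     replace = TRUE),
              sample(3:9, length(fails), replace = TRUE))
    ids <- sprintf("%03d-%03d_%d", seq_along(smiles) * 3,
                   seq_along(smiles) * 3 + 2, seq_along(smiles) %% 4)
    ids[1] <- "339-342_1"  # the planted best ring keeps its field id
    mols <- smiles_to_mol(stats::setNames(unname(smiles), ids),
                          source = "fixture")
    rings <- lapply(seq_along(mols), function(i)
      ring_system(mols[[i]], ring_id = ids[i], frequency = freq[i]))
    descs <- lapply(mols, descriptor_set)
    # verify the plant against the actually computed descriptors
    pass_v <- vapply(descs, function(d) d$vabc > 140, logical(1))
    pass_h <- vapply(descs, function(d) d$hba + d$hbd < 3, logical(1))
    i_surv <- seq_along(surv)
    i_polar <- length(surv) + seq_along(polar)
    i_small <- length(surv) + length(polar) + seq_along(small)
    if (!all(pass_v[i_surv] & pass_h[i_surv]) ||
        (length(polar) && !all(pass_v[i_polar] & !pass_h[i_polar])) ||
        (length(small) && any(pass_v[i_small])))
      stop("infeasible plant: vocabulary descriptors violate the design")
    list(rings = rings, descriptors = descs,
         planted = list(
           best_ring = ids[1],
           survivors = ids[seq_along(surv)],
           untypeable = if (spec$n_untypeable > 0)
             ids[2L + seq_len(spec$n_untypeable)] else character(),
           scaffold = stats::setNames(names(smiles), ids)))
  })
}

# drug-like co-crystal ligand vocabulary for surviving targets (MW 250-800,
# carbon present, representative-ligand HBA < 5 and HBD < 2)
.ligand_vocab <- c(
  cyproheptadine = "CN1CCC(=C2c3ccccc3C=Cc3ccccc32)CC1",
  pyrene_butyrate = "CCOC(=O)CCCc1ccc2ccc3cccc4ccc1c2c34",
  oxcarbazepine = "NC(=O)N1c2ccccc2CC(=O)c2ccccc21",
  testosterone = "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
  stearic_acid = "CCCCCCCCCCCCCCCCCC(=O)O",
  phenanthrene_ester = "CCOC(=O)Cc1cc2ccccc2c2ccccc12",
  fluorenone_amine = "CN(C)CCOC1c2ccccc2-c2ccccc21")

#' Generate a synthetic target set
#'
#' Builds `n_targets` records with controlled PDB counts, co-crystal
#' ligands, development labels and known-ligand counts so that exactly
#' `n_pass_targets` survive [filter_targets()].  Two ground truths are
#' planted among the survivors: the mutual-best pair (the target whose
#' reference ligand is cyproheptadine, a shape match of the planted ring)
#' and a saddle target whose ring-free chain ligand scores every ring
#' poorly, making its row-best ring a poorly-ranked column entry.
#'
#' @param spec a `fixture_spec`.
#' @return list with `targets` (target_record list) and `planted` (ids of
#'   the mutual-best target/ring and the saddle target).
#' @export
make_target_set <- function(spec) {
  .with_seed(spec$seed + 1L, function() {
    n <- spec$n_targets; npass <- spec$n_pass_targets
    ids <- sprintf("T%02d", seq_len(n))
    mb_target <- ids[1]; saddle_target <- ids[2]
    lig_smis <- .ligand_vocab
    targets <- vector("list", n)
    pdb_code <- function(i, k) sprintf("%d%s%02d", (i %% 9) + 1,
                                       LETTERS[(i %% 26) + 1], k)
    for (i in seq_len(n)) {
      passing <- i <= npass
      pool <- setdiff(names(lig_smis), c("cyproheptadine", "stearic_acid"))
      lig_name <- if (ids[i] == mb_target) "cyproheptadine"
        else if (ids[i] == saddle_target) "stearic_acid"
        else pool[1L + (i %% length(pool))]
      lig <- smiles_to_mol(
        stats::setNames(lig_smis[[lig_name]], paste0(ids[i], "_lig")),
        source = "fixture")[[1]]
      npdb <- if (passing) 6L + (i %% 3L) else 3L
      rec <- target_record(
        uniprot = ids[i],
        pdb_ids = vapply(seq_len(npdb), function(k) pdb_code(i, k),
                         character(1)),
        ligands = list(lig),
        development_label = if (passing) "clinical" else "research",
        chembl_ligand_count = if (passing) 150L + 10L * i else 150L,
        in_clinical_table = TRUE, in_ligand_table = TRUE)
      if (!passing) {
        # designed single violations, cycling through the criteria
        mode <- i %% 4L
        if (mode == 0L) rec$pdb_ids <- rec$pdb_ids[1:3]
        if (mode == 1L) rec$ligands <- list()
        if (mode == 2L) rec$chembl_ligand_count <- 80L
        if (mode == 3L) rec$in_clinical_table <- FALSE
        if (mode != 0L && length(rec$pdb_ids) < 6L)
          rec$pdb_ids <- vapply(seq_len(6L), function(k) pdb_code(i, k),
                                character(1))
      }
      targets[[i]] <- rec
    }
    names(targets) <- ids
    list(targets = targets,
         planted = list(mutual_best_target = mb_target,
                        mutual_best_ring = "339-342_1",
                        saddle_target = saddle_target))
  })
}

# aryl bromide reagents: the eight benchmark substituent patterns
# (positions R1..R5 = ortho, meta, para, meta', ortho' on N-phenyl), plus
# simple extras
.reagent_vocab <- c(
  r6a = "Brc1ccc(C)c(C(=O)O)c1",          # R2 = COOH, R3 = CH3
  r6b = "Brc1ccc(C(=O)O)c(C)c1",          # R2 = CH3,  R3 = COOH
  r6c = "Brc1ccc(C(=O)O)cc1",             # R3 = COOH
  r6d = "O=[N+]([O-])c1cc(ccc1Br)C(=O)O", # R1 = NO2,  R3 = COOH
  r6e = "Brc1cccc(C(=O)O)c1",             # R2 = COOH
  r6f = "Brc1ccccc1C(=O)O",               # R1 = COOH
  r8a = "Nc1cc(ccc1Br)C(=O)O",            # R1 = NH2,  R3 = COOH
  r8b = "Brc1cc(N)cc(C(=O)O)c1",          # R2 = NH2,  R4 = COOH
  bromobenzene = "Brc1ccccc1",
  styryl_bromide = "Br/C=C/c1ccccc1",
  tolyl_bromide = "Brc1ccc(C)cc1",
  anisyl_bromide = "COc1ccc(Br)cc1")

#' Generate a synthetic reagent set
#'
#' The first eight reagents carry the benchmark substituent patterns
#' (carboxyl, methyl, nitro, amino at varied phenyl positions) so the
#' reference N-aryl products are constructible; extras are simple aryl or
#' vinyl bromides.
#'
#' @param spec a `fixture_spec`.
#' @return A list of `reagent` objects (named).
#' @export
make_reagents <- function(spec) {
  n <- min(spec$n_reagents, length(.reagent_vocab))
  smis <- .reagent_vocab[seq_len(n)]
  mols <- smiles_to_mol(smis, source = "fixture")
  lapply(mols, reagent_record)
}

#' Write fixture files in the formats the pipeline readers consume
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the files written (`rings_smi`,
#'   `rings_csv`, `targets_csv`, `ligands_smi`, `reagents_smi`,
#'   `planted_json`).
#' @export
write_fixture_files <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rt <- make_ring_table(spec)
  ts <- make_target_set(spec)
  rg <- make_reagents(spec)
  paths <- list(rings_smi = file.path(dir, "rings.smi"),
                rings_csv = file.path(dir, "rings.csv"),
                targets_csv = file.path(dir, "targets.csv"),
                ligands_smi = file.path(dir, "ligands.smi"),
                reagents_smi = file.path(dir, "reagents.smi"),
                planted_json = file.path(dir, "planted.json"))
  writeLines(vapply(rt$rings, function(r)
    paste(canonical_smiles(r$mol), r$ring_id), character(1)),
    paths$rings_smi)
  write_descriptor_table(rt$rings, rt$descriptors, paths$rings_csv)
  tdf <- do.call(rbind, lapply(ts$targets, function(t) data.frame(
    uniprot = t$uniprot, pdb_ids = paste(t$pdb_ids, collapse = ";"),
    development_label = t$development_label,
    chembl_ligand_count = t$chembl_ligand_count,
    in_clinical_table = t$in_clinical_table,
    in_ligand_table = t$in_ligand_table,
    ligand_ids = paste(vapply(t$ligands, function(l) l$id, character(1)),
                       collapse = ";"))))
  utils::write.csv(tdf, paths$targets_csv, row.names = FALSE)
  ligs <- unlist(lapply(ts$targets, function(t) t$ligands),
                 recursive = FALSE)
  writeLines(vapply(ligs, function(l)
    paste(canonical_smiles(l), l$id), character(1)), paths$ligands_smi)
  writeLines(vapply(rg, function(r)
    paste(canonical_smiles(r$mol), r$mol$id), character(1)),
    paths$reagents_smi)
  jsonlite::write_json(c(rt$planted[c("best_ring", "untypeable")],
                         ts$planted),
                       paths$planted_json, auto_unbox = TRUE)
  invisible(paths)
}

#' Read a target metadata table written by [write_fixture_files()]
#'
#' @param targets_csv CSV with the documented target columns.
#' @param ligands_smi SMILES file of co-crystal ligands (ids referenced by
#'   the CSV's `ligand_ids` column).
#' @return A list of `target_record` objects.
#' @export
read_target_table <- function(targets_csv, ligands_smi) {
  tab <- utils::read.csv(targets_csv, stringsAsFactors = FALSE)
  ligs <- parse_structures(ligands_smi, "smiles")
  lapply(seq_len(nrow(tab)), function(i) {
    lid <- strsplit(tab$ligand_ids[i], ";")[[1]]
    lid <- lid[nzchar(lid)]
    target_record(uniprot = tab$uniprot[i],
                  pdb_ids = strsplit(tab$pdb_ids[i], ";")[[1]],
                  ligands = unname(ligs[lid]),
                  development_label = tab$development_label[i],
                  chembl_ligand_count = tab$chembl_ligand_count[i],
                  in_clinical_table = tab$in_clinical_table[i],
                  in_ligand_table = tab$in_ligand_table[i])
  })
}
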