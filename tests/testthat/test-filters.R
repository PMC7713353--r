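ring_with <- function(id, vabc, hba, hbd, freq) {
  list(ring = ring_system(tr_mols()$naphthalene, ring_id = id,
                          frequency = freq),
       desc = data.frame(vabc = vabc, hba = hba, hbd = hbd))
}

test_that("ring funnel applies strict thresholds in order", {
  items <- list(
    ring_with("keep", vabc = 150, hba = 1, hbd = 1, freq = 2),
    ring_with("low_vol", vabc = 81.18, hba = 0, hbd = 0, freq = 0),
    ring_with("polar", vabc = 180, hba = 2, hbd = 1, freq = 1),
    ring_with("common", vabc = 200, hba = 0, hbd = 0, freq = 5),
    ring_with("boundary_vabc", vabc = 140, hba = 0, hbd = 0, freq = 0),
    ring_with("boundary_hahb", vabc = 150, hba = 2, hbd = 0, freq = 0))
  res <- filter_ring_systems(lapply(items, `[[`, "ring"),
                             lapply(items, `[[`, "desc"))
  kept <- vapply(res$kept, function(r) r$ring_id, character(1))
  # vabc > 140 strict, hba + hbd < 3 strict, frequency < 3 strict;
  # hba + hbd == 2 passes, vabc == 140 fails
  expect_setequal(kept, c("keep", "boundary_hahb"))
  fs <- funnel_summary(res$funnel)
  expect_equal(fs$stage, c("frequency", "vabc", "hahb"))
  expect_equal(fs$n_in, c(6, 5, 3))
  expect_equal(fs$n_out, c(5, 3, 2))
})

test_that("missing descriptors fail with the documented reason", {
  items <- list(ring_with("ok", 150, 0, 0, 0),
                ring_with("nodesc", NA, 0, 0, 0))
  res <- filter_ring_systems(lapply(items, `[[`, "ring"),
                             lapply(items, `[[`, "desc"))
  rep <- res$funnel[[2]]
  expect_equal(rep$items$reason[rep$items$id == "nodesc"],
               "missing descriptor")
})

test_that("funnel stages conserve counts and are order-stable", {
  set.seed(31)
  items <- lapply(seq_len(30), function(i)
    ring_with(sprintf("r%02d", i), vabc = runif(1, 100, 250),
              hba = sample(0:3, 1), hbd = sample(0:2, 1),
              freq = sample(0:5, 1)))
  res <- filter_ring_systems(lapply(items, `[[`, "ring"),
                             lapply(items, `[[`, "desc"))
  fs <- funnel_summary(res$funnel)
  expect_equal(fs$n_in[-1], fs$n_out[-length(fs$n_out)])
  perm <- sample(length(items))
  res2 <- filter_ring_systems(lapply(items[perm], `[[`, "ring"),
                              lapply(items[perm], `[[`, "desc"))
  expect_setequal(vapply(res2$kept, function(r) r$ring_id, character(1)),
                  vapply(res$kept, function(r) r$ring_id, character(1)))
  # loosening a threshold never shrinks the kept set
  res3 <- filter_ring_systems(lapply(items, `[[`, "ring"),
                              lapply(items, `[[`, "desc"),
                              vabc_min = 120)
  expect_true(all(vapply(res$kept, function(r) r$ring_id, character(1)) %in%
                    vapply(res3$kept, function(r) r$ring_id, character(1))))
})

make_target <- function(id, npdb = 6, lig = "cyproheptadine",
                        label = "clinical", count = 150,
                        clinical = TRUE, known = TRUE) {
  ligands <- if (is.null(lig)) list() else {
    l <- tr_mols()[[lig]]
    l$id <- paste0(id, "_lig")
    list(l)
  }
  target_record(id, pdb_ids = sprintf("%s%02d", id, seq_len(npdb)),
                ligands = ligands, development_label = label,
                chembl_ligand_count = count, in_clinical_table = clinical,
                in_ligand_table = known)
}

test_that("target boundary cases follow the strict readings", {
  res <- filter_targets(list(
    make_target("T1", npdb = 5),          # "more than five" read strictly
    make_target("T2", count = 100),       # "> 100" strict
    make_target("T3")))                   # passes everything
  kept <- vapply(res$kept, function(t) t$uniprot, character(1))
  expect_equal(kept, "T3")
  expect_equal(res$funnel[[1]]$items$pass,
               c(FALSE, TRUE, TRUE))
})

test_that("a designed 50-target table keeps exactly the planted 7", {
  targets <- c(
    lapply(sprintf("P%02d", 1:7), make_target),
    lapply(8:20, function(i) make_target(sprintf("P%02d", i), npdb = 4)),
    lapply(21:30, function(i) make_target(sprintf("P%02d", i), lig = NULL)),
    lapply(31:40, function(i) make_target(sprintf("P%02d", i), count = 50)),
    lapply(41:47, function(i) make_target(sprintf("P%02d", i),
                                          clinical = FALSE)),
    lapply(48:50, function(i) make_target(sprintf("P%02d", i),
                                          lig = "benzoic_acid")))  # MW < 250
  res <- filter_targets(targets)
  expect_length(res$kept, 7)
  # independent per-row check of the same criteria
  manual <- vapply(targets, function(t) {
    length(t$pdb_ids) >= 6 && length(t$ligands) >= 1 &&
      t$in_clinical_table && t$in_ligand_table &&
      t$chembl_ligand_count > 100 &&
      any(vapply(t$ligands, function(l) {
        w <- mol_weight(l)
        any(l$atoms$elem == "C") && w >= 250 && w <= 800
      }, logical(1)))
  }, logical(1))
  expect_equal(sum(manual), 7)
  expect_setequal(vapply(res$kept, function(t) t$uniprot, character(1)),
                  vapply(targets[manual], function(t) t$uniprot,
                         character(1)))
})

test_that("duplicate PDB codes are de-duplicated before counting", {
  t <- target_record("T", pdb_ids = c("1ABC", "1ABC", "2DEF"),
                     ligands = list())
  expect_length(t$pdb_ids, 2)
})

test_that("PDB ligand filter removes the designed violators", {
  m <- tr_mols()
  big_chain <- smiles_to_mol(
    paste(rep("C", 64), collapse = ""))[[1]]    # MW ~ 900
  phosphate <- smiles_to_mol("OP(=O)(O)O")[[1]] # carbon-free
  ligs <- c(rep(list(m$cyproheptadine), 4),
            list(m$cyproheptadine, m$cyproheptadine),  # successful targets
            list(big_chain, phosphate),
            rep(list(m$cyproheptadine), 2))
  for (i in seq_along(ligs)) ligs[[i]]$id <- sprintf("L%02d", i)
  labels <- c(rep("clinical", 4), "successful", "successful",
              rep("clinical", 4))
  res <- filter_pdb_ligands(ligs, labels)
  expect_length(res$kept, 6)
  expect_equal(res$report$n_in, 10)
  expect_equal(res$report$n_out, 6)
  reasons <- res$report$items$reason
  expect_equal(sum(grepl("successful", reasons), na.rm = TRUE), 2)
  expect_equal(sum(grepl("inorganic", reasons), na.rm = TRUE), 1)
  expect_equal(sum(grepl("MW", reasons), na.rm = TRUE), 1)
})
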