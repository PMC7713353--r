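nor_core <- function() {
  m <- tr_mols()$norcyproheptadine
  core_scaffold(m, which(m$atoms$elem == "N"))
}

test_that("coupling reproduces the benchmark product structures", {
  rg <- smiles_to_mol(c(r6c = "OC(=O)c1ccc(Br)cc1",
                        rphenyl = "Brc1ccccc1"))
  prods <- enumerate_n_arylation(nor_core(), rg)
  expect_length(prods, 2)
  expect_equal(mol_formula_string(prods[[1]]$mol), "C27H23NO2")
  expect_equal(prods[[1]]$heavy_atom_count, 30L)
  # core (21 heavy) + bromobenzene (7 heavy) - Br
  expect_equal(prods[[2]]$heavy_atom_count, 27L)
})

test_that("reagents without a qualifying C-Br are skipped", {
  rg <- smiles_to_mol(c(nobr = "c1ccccc1", alkyl_br = "CCBr"))
  w <- capture_warnings(prods <- enumerate_n_arylation(nor_core(), rg))
  expect_length(w, 2)
  expect_match(w, "C-Br", all = TRUE)
  expect_length(prods, 0)
  expect_setequal(attr(prods, "skipped"), c("nobr", "alkyl_br"))
})

test_that("vinyl bromides couple like aryl bromides", {
  rg <- smiles_to_mol(c(styryl = "Br/C=C/c1ccccc1"))
  prods <- enumerate_n_arylation(nor_core(), rg)
  expect_length(prods, 1)
  # styryl bromide has 9 heavy atoms (8 C + Br); the bromide leaves
  expect_equal(prods[[1]]$heavy_atom_count, 21L + 9L - 1L)
})

test_that("enumeration conserves mass: product + HBr = core + reagent", {
  spec <- fixture_spec(seed = 2)
  reagents <- make_reagents(spec)
  core <- nor_core()
  prods <- enumerate_n_arylation(core, reagents)
  expect_length(prods, length(reagents))   # no duplicates, no losses
  add_formula <- function(a, b) {
    all_e <- union(names(a), names(b))
    stats::setNames(vapply(all_e, function(e)
      (if (e %in% names(a)) a[[e]] else 0L) +
        (if (e %in% names(b)) b[[e]] else 0L), integer(1)), all_e)
  }
  hbr <- c(H = 1L, Br = 1L)
  for (i in seq_along(prods)) {
    lhs <- add_formula(mol_formula(prods[[i]]$mol), hbr)
    rhs <- add_formula(mol_formula(core$mol),
                       mol_formula(reagents[[i]]$mol))
    expect_equal(lhs[sort(names(lhs))], rhs[sort(names(rhs))],
                 info = prods[[i]]$mol$id)
  }
})

test_that("ligand efficiency reproduces the eight benchmark rows", {
  reagents <- make_reagents(fixture_spec())[1:8]
  prods <- enumerate_n_arylation(nor_core(), reagents)
  printed <- data.frame(
    reagent = c("r6a", "r6b", "r6c", "r6d", "r6e", "r6f", "r8a", "r8b"),
    score = c(-11.506, -15.324, -15.568, -12.220, -11.569, -8.404,
              -12.994, -14.352),
    le = c(-0.371, -0.494, -0.519, -0.370, -0.386, -0.280, -0.419, -0.463))
  for (k in seq_len(nrow(printed))) {
    p <- prods[[paste0("norcyproheptadine~", printed$reagent[k])]]
    expect_false(is.null(p))
    expect_equal(round(ligand_efficiency(printed$score[k], p$mol), 3),
                 printed$le[k], info = printed$reagent[k])
  }
  # heavy-atom counts behind those ratios
  counts <- vapply(prods, function(p) p$heavy_atom_count, integer(1))
  expect_equal(unname(counts[paste0("norcyproheptadine~",
                                    printed$reagent)]),
               c(31L, 31L, 30L, 33L, 30L, 30L, 31L, 31L))
  # degenerate cases
  expect_equal(ligand_efficiency(0, tr_mols()$benzene), 0)
  single <- smiles_to_mol("[C]")[[1]]
  expect_equal(ligand_efficiency(-1, single), -1)
})

test_that("PSA follows the topological contribution scheme", {
  m <- tr_mols()
  expect_equal(compute_psa(m$benzene), 0)
  expect_equal(compute_psa(m$ethane), 0)
  expect_equal(compute_psa(m$benzoic_acid), 37.3, tolerance = 1e-6)
})

test_that("the PAINS catalog subset flags its exemplars and passes clean rings", {
  m <- smiles_to_mol(c(benzene = "c1ccccc1",
                       para_quinone = "O=C1C=CC(=O)C=C1",
                       rhodanine = "O=C1CSC(=S)N1",
                       catechol = "Oc1ccccc1O",
                       azo = "c1ccccc1/N=N/c1ccccc1"))
  pf <- pains_filter(m)
  expect_true(pf[["benzene"]])
  expect_false(pf[["para_quinone"]])
  expect_false(pf[["rhodanine"]])
  expect_false(pf[["catechol"]])
  expect_false(pf[["azo"]])
  # the benchmark carboxylate product passes
  prods <- enumerate_n_arylation(
    nor_core(), smiles_to_mol(c(r6c = "OC(=O)c1ccc(Br)cc1")))
  expect_true(prods[[1]]$pains_pass)
})

test_that("protonated amides are detected via the ionization SMARTS", {
  m <- smiles_to_mol(c(prot = "CC(=O)[NH3+]", neutral = "CC(=O)N",
                       amine = "CC[NH3+]"))
  sdfset <- trscreen:::mols_to_sdfset(m)
  hits <- as.numeric(ChemmineR::smartsSearchOB(
    sdfset, trscreen:::.protonated_amide_smarts, uniqueMatches = TRUE))
  expect_equal(hits > 0, c(TRUE, FALSE, FALSE), ignore_attr = TRUE)
})

test_that("the drug-likeness filter removes the designed violators", {
  mkp <- function(id, ro5 = 0L, ro3 = 0L, pa = FALSE) {
    structure(list(mol = list(id = id), ro5_violations = as.integer(ro5),
                   ro3_violations = as.integer(ro3),
                   protonated_amide = pa),
              class = "product_record")
  }
  prods <- c(lapply(sprintf("ok%d", 1:7), mkp),
             list(mkp("v1", ro5 = 2L), mkp("v2", ro3 = 1L),
                  mkp("v3", pa = TRUE)))
  expect_message(res <- druglikeness_filter(prods), "predictor")
  expect_length(res$kept, 7)
  expect_equal(res$report$n_out, 7)
  # external predictor values activate the pass-through thresholds
  pred <- data.frame(herg = c(rep(0, 7), NA, NA, NA),
                     oral = c(90, rep(85, 6), NA, NA, NA),
                     row.names = sapply(prods, function(p) p$mol$id))
  pred$herg[2] <- -6
  res2 <- druglikeness_filter(prods, predicted = pred)
  expect_length(res2$kept, 6)
})
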