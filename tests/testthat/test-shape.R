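test_that("identical single atoms overlap completely; distant ones do not", {
  c1 <- conformer("a", matrix(0, 1, 3), "C")
  c2 <- conformer("b", matrix(0, 1, 3), "C")
  v <- gaussian_overlap_volume(c1, c2)
  expect_equal(v[["V_AB"]], v[["V_AA"]])
  expect_equal(v[["V_AB"]], v[["V_BB"]])
  far <- conformer("c", matrix(c(50, 0, 0), 1, 3), "C")
  expect_lt(gaussian_overlap_volume(c1, far)[["V_AB"]], 1e-6)
})

test_that("pairwise overlap volumes agree with grid integration within 2%", {
  set.seed(91)
  radii_pool <- c(1.2, 1.52, 1.55, 1.7, 1.8)
  for (rep in 1:6) {
    na <- sample(2:5, 1); nb <- sample(1:5, 1)
    xa <- matrix(runif(3 * na, -1.5, 1.5), na, 3)
    xb <- matrix(runif(3 * nb, -1.5, 1.5), nb, 3)
    ra <- sample(radii_pool, na, replace = TRUE)
    rb <- sample(radii_pool, nb, replace = TRUE)
    A <- conformer("A", xa, rep("C", na)); A$radii <- ra
    B <- conformer("B", xb, rep("C", nb)); B$radii <- rb
    v <- gaussian_overlap_volume(A, B)
    oracle <- grid_overlap_oracle(xa, ra, xb, rb)
    expect_lt(abs(v[["V_AB"]] - oracle) / oracle, 0.02)
  }
})

test_that("self-overlay scores are exactly one", {
  cf <- tr_confs("naphthalene")[[1]]
  s <- score_overlay(align_overlay(cf, cf, tr_mols()$naphthalene,
                                   tr_mols()$naphthalene))
  expect_equal(s$shape_tanimoto, 1, tolerance = 1e-6)
  expect_equal(s$color_tanimoto, 1, tolerance = 1e-6)
  expect_equal(s$tanimoto_combo_norm, 1, tolerance = 1e-6)
  expect_equal(s$ref_tversky_shape, 1, tolerance = 1e-6)
})

test_that("alignment recovers arbitrary rigid transforms", {
  set.seed(17)
  for (nm in c("naphthalene", "cyproheptadine")) {
    cf <- tr_confs(nm)[[1]]
    w <- runif(3, -pi, pi)
    R <- trscreen:::.rodrigues(w)
    moved <- cf
    moved$coords <- cf$coords %*% t(R) +
      rep(1, nrow(cf$coords)) %o% runif(3, -5, 5)
    s <- score_overlay(align_overlay(moved, cf, tr_mols()[[nm]],
                                     tr_mols()[[nm]]))
    expect_gte(s$shape_tanimoto, 0.99)
  }
})

test_that("similarity ordering separates identical, related and disjoint shapes", {
  cfs <- tr_confs(c("benzene", "naphthalene"))
  m <- tr_mols()
  self <- score_overlay(align_overlay(cfs$benzene, cfs$benzene,
                                      m$benzene, m$benzene))
  rel <- score_overlay(align_overlay(cfs$benzene, cfs$naphthalene,
                                     m$benzene, m$naphthalene))
  expect_lt(rel$shape_tanimoto, self$shape_tanimoto)
  expect_gt(rel$shape_tanimoto, 0.2)
})

test_that("Tanimoto is symmetric; Tversky favours the reference", {
  cfs <- tr_confs(c("benzene", "naphthalene"))
  m <- tr_mols()
  ab <- score_overlay(align_overlay(cfs$benzene, cfs$naphthalene,
                                    m$benzene, m$naphthalene))
  ba <- score_overlay(align_overlay(cfs$naphthalene, cfs$benzene,
                                    m$naphthalene, m$benzene))
  expect_equal(ab$shape_tanimoto, ba$shape_tanimoto, tolerance = 0.02)
  # small query against large reference is penalized by RefTversky and
  # rewarded in the swapped direction
  expect_lt(ab$ref_tversky_shape, ba$ref_tversky_shape)
})

test_that("scores stay within their ranges on random pairs", {
  pool <- c("benzene", "naphthalene", "phenol", "pyridine", "butane",
            "anthraquinone", "toluene", "cyproheptadine")
  cfs <- tr_confs(pool)
  m <- tr_mols()
  set.seed(23)
  for (k in 1:10) {
    pick <- sample(pool, 2)
    s <- score_overlay(align_overlay(cfs[[pick[1]]], cfs[[pick[2]]],
                                     m[[pick[1]]], m[[pick[2]]]))
    expect_gte(s$shape_tanimoto, 0); expect_lte(s$shape_tanimoto, 1 + 1e-9)
    expect_gte(s$color_tanimoto, 0); expect_lte(s$color_tanimoto, 1 + 1e-9)
    expect_gte(s$tanimoto_combo, 0); expect_lte(s$tanimoto_combo, 2 + 1e-9)
    expect_gte(s$tanimoto_combo_norm, 0)
    expect_lte(s$tanimoto_combo_norm, 1 + 1e-9)
    expect_lte(s$ref_tversky_combo_norm, 1 + 1e-9)
    # the first-order cross sum tracks the smaller self-overlap, up to a
    # small size-mismatch excess
    v <- gaussian_overlap_volume(cfs[[pick[1]]], cfs[[pick[2]]])
    expect_lte(v[["V_AB"]], 1.05 * min(v[["V_AA"]], v[["V_BB"]]))
  }
})

test_that("a featureless query scores zero color similarity", {
  cfs <- tr_confs(c("cf4", "benzene"))
  m <- tr_mols()
  expect_equal(nrow(feature_points(m$cf4,
                                   cfs$cf4$coords[1:5, , drop = FALSE])), 0)
  s <- score_overlay(align_overlay(cfs$cf4, cfs$benzene, m$cf4, m$benzene))
  expect_equal(s$color_tanimoto, 0)
})

test_that("degenerate overlays raise an error", {
  ov <- structure(list(query_id = "q", ref_id = "r", V_AB = 0, V_AA = 0,
                       V_BB = 1, C_AB = 0, C_AA = 0, C_BB = 0),
                  class = "overlay")
  expect_error(score_overlay(ov), "degenerate")
})

test_that("feature typing follows the embedded rules", {
  m <- tr_mols()$phenol
  cf <- tr_confs("phenol")[[1]]
  fp <- feature_points(m, cf$coords[seq_len(cf$n_heavy), , drop = FALSE])
  expect_setequal(unique(fp$type),
                  c("donor", "acceptor", "ring", "hydrophobe"))
  expect_equal(sum(fp$type == "ring"), 1)
  charged <- smiles_to_mol("C[NH3+]")[[1]]
  cc <- generate_conformers(charged, n = 1, seed = 3)[[1]]
  fp2 <- feature_points(charged,
                        cc$coords[seq_len(cc$n_heavy), , drop = FALSE])
  expect_true("cation" %in% fp2$type)
})
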