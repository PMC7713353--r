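named_matrix <- function(v, nr, nc) {
  matrix(v, nr, nc, dimnames = list(sprintf("t%02d", seq_len(nr)),
                                    sprintf("r%02d", seq_len(nc))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rank transform follows the most-negative-first convention", {
  m <- named_matrix(c(-10, -5), 1, 2)
  expect_equal(unname(rank_transform(m, "rows")[1, ]), c(1L, 2L))
  # ties broken deterministically by id
  m2 <- named_matrix(c(-4, -4, -9), 1, 3)
  colnames(m2) <- c("a", "b", "c")
  expect_equal(unname(rank_transform(m2, "rows")[1, ]), c(2L, 3L, 1L))
})

test_that("ranks agree with a sort-based oracle and survive monotone maps", {
  set.seed(19)
  for (dims in list(c(10, 8), c(20, 20))) {
    m <- named_matrix(round(rnorm(prod(dims), -6, 2), 3), dims[1], dims[2])
    m[sample(length(m), 5)] <- NA
    rr <- rank_transform(m, "rows")
    for (i in seq_len(nrow(m))) {
      ok <- which(!is.na(m[i, ]))
      oracle <- ok[order(m[i, ok], colnames(m)[ok])]
      expect_equal(rr[i, oracle], seq_along(oracle), ignore_attr = TRUE)
      expect_true(all(is.na(rr[i, setdiff(seq_len(ncol(m)), ok)])))
      # each ranked vector is a permutation of 1..k
      expect_setequal(rr[i, ok], seq_along(ok))
    }
    # strictly monotone transform of scores leaves ranks unchanged
    m2 <- m; m2[] <- -exp(-m2) # increasing in m
    expect_equal(unclass(rank_transform(m2, "rows")), unclass(rr),
                 ignore_attr = TRUE)
    cr <- rank_transform(m, "columns")
    for (j in seq_len(ncol(m))) {
      ok <- which(!is.na(m[, j]))
      oracle <- ok[order(m[ok, j], rownames(m)[ok])]
      expect_equal(cr[oracle, j], seq_along(oracle), ignore_attr = TRUE)
    }
  }
})

test_that("all-missing vectors are flagged, not ranked", {
  m <- named_matrix(c(-1, NA, -2, NA), 2, 2)
  m[2, ] <- NA
  rr <- rank_transform(m, "rows")
  expect_true(all(is.na(rr[2, ])))
  expect_equal(attr(rr, "unranked"), "t02")
})

test_that("mutual-best pairs match the 2x2 worked example and brute force", {
  m <- named_matrix(c(-9, -2, -1, -8), 2, 2)  # column-major
  rr <- rank_transform(m, "rows"); cr <- rank_transform(m, "columns")
  mb <- mutual_best_pairs(rr, cr, m)
  expect_equal(nrow(mb), 2)
  expect_setequal(paste(mb$target_id, mb$ring_id),
                  c("t01 r01", "t02 r02"))

  # a structured 3x3: exhaustive double-loop check of the definition
  m2 <- named_matrix(c(-1, -9, -5, -8, -2, -4, -3, -7, -6), 3, 3)
  rr2 <- rank_transform(m2, "rows"); cr2 <- rank_transform(m2, "columns")
  mb2 <- mutual_best_pairs(rr2, cr2)
  brute <- sum(sapply(seq_len(3), function(i) sapply(seq_len(3), function(j)
    m2[i, j] == min(m2[i, ]) && m2[i, j] == min(m2[, j]))))
  expect_equal(nrow(mb2), brute)
  # the cell holding the global minimum is always a mutual best
  gmin <- which(m2 == min(m2), arr.ind = TRUE)
  expect_true(any(mb2$target_id == rownames(m2)[gmin[1, 1]] &
                    mb2$ring_id == colnames(m2)[gmin[1, 2]]))

  set.seed(29)
  for (k in 1:5) {
    m3 <- named_matrix(rnorm(16), 4, 4)
    rr3 <- rank_transform(m3, "rows"); cr3 <- rank_transform(m3, "columns")
    mb3 <- mutual_best_pairs(rr3, cr3)
    brute3 <- which(outer(seq_len(4), seq_len(4), Vectorize(function(i, j)
      m3[i, j] == min(m3[i, ]) && m3[i, j] == min(m3[, j]))),
      arr.ind = TRUE)
    expect_equal(nrow(mb3), nrow(brute3))
    if (nrow(mb3))
      expect_setequal(paste(mb3$target_id, mb3$ring_id),
                      paste(rownames(m3)[brute3[, 1]],
                            colnames(m3)[brute3[, 2]]))
  }
})

test_that("saddle points match their definition, and mutual bests are never saddles", {
  # row 1: ring r01 is the target's best but the worst target for r01
  m <- named_matrix(c(-9, -10, -8, -1), 2, 2)
  rr <- rank_transform(m, "rows"); cr <- rank_transform(m, "columns")
  sp <- saddle_points(rr, cr)
  expect_true(any(sp$target_id == "t01" & sp$ring_id == "r01"))
  mb <- mutual_best_pairs(rr, cr)
  if (nrow(mb) && nrow(sp))
    expect_false(any(paste(mb$target_id, mb$ring_id) %in%
                       paste(sp$target_id, sp$ring_id)))

  set.seed(37)
  for (dims in list(c(10, 10), c(20, 20))) {
    m2 <- named_matrix(rnorm(prod(dims)), dims[1], dims[2])
    rr2 <- rank_transform(m2, "rows"); cr2 <- rank_transform(m2, "columns")
    sp2 <- saddle_points(rr2, cr2, good_rank = 1, bad_quantile = 0.5)
    # brute-force definition scan
    brute <- list()
    for (i in seq_len(nrow(m2))) for (j in seq_len(ncol(m2))) {
      if (rr2[i, j] == 1 && cr2[i, j] > nrow(m2) * 0.5)
        brute[[length(brute) + 1L]] <- c(i, j, "ring_for_target")
      if (cr2[i, j] == 1 && rr2[i, j] > ncol(m2) * 0.5)
        brute[[length(brute) + 1L]] <- c(i, j, "target_for_ring")
    }
    expect_equal(nrow(sp2), length(brute))
    if (length(brute))
      expect_setequal(
        paste(sp2$target_id, sp2$ring_id, sp2$good_axis),
        vapply(brute, function(b)
          paste(rownames(m2)[as.integer(b[1])],
                colnames(m2)[as.integer(b[2])], b[3]), character(1)))
    expect_true(all(sp2$saddle_index > 0 & sp2$saddle_index <= 1))
    # mutual bests always carry saddle index zero by definition
    mb2 <- mutual_best_pairs(rr2, cr2)
    if (nrow(mb2))
      expect_false(any(paste(mb2$target_id, mb2$ring_id) %in%
                         paste(sp2$target_id, sp2$ring_id)))
  }
})

test_that("dock_all merges per-PDB scores, excludes untypeable rings, and is order-stable", {
  m <- tr_mols()
  rings <- list(ring_system(m$benzene, "rA", 0L),
                ring_system(m$naphthalene, "rB", 0L),
                ring_system(smiles_to_mol(
                  c(se = "c1ccc2c(c1)[se]c1ccccc12"))[[1]], "rSe", 0L))
  lig1 <- m$phenol; lig1$id <- "L1"
  lig2 <- m$pyridine; lig2$id <- "L2"
  t1 <- target_record("T1", c("1AAA", "1AAB"), list(lig1, lig2))
  t2 <- target_record("T2", "2AAA", list(lig2))
  # deterministic synthetic scorer: depends on ring size and which PDB
  # ligand is the reference
  sc <- tr_scorer("synthetic", function(target, ring, ring_confs, ref) {
    -(n_heavy_atoms(ring$mol) + as.numeric(sub(".*#", "", ref$mol$id)))
  })
  sm <- dock_all(rings, list(t1, t2), sc, seed = 5)
  expect_equal(sm$excluded_rings$ring_id, "rSe")
  expect_equal(sm$excluded_rings$reason, "missing atom types")
  expect_equal(colnames(sm$scores), c("rA", "rB"))
  # T1 has two PDBs scoring -(n+1) and -(n+2): merged best is -(n+2)
  expect_equal(sm$scores["T1", "rA"], -(6 + 2))
  expect_equal(sm$scores["T1", "rB"], -(10 + 2))
  expect_equal(sm$scores["T2", "rA"], -(6 + 1))
  # mean merge
  sm2 <- dock_all(rings, list(t1, t2), sc, seed = 5, merge = "mean")
  expect_equal(sm2$scores["T1", "rA"], -(6 + 1.5))
  # identical under reordering of rings and targets
  sm3 <- dock_all(rev(rings), list(t2, t1), sc, seed = 5)
  expect_equal(sm3$scores[rownames(sm$scores), colnames(sm$scores)],
               sm$scores)
})

test_that("scorer failures become missing cells with logged reasons", {
  m <- tr_mols()
  rings <- list(ring_system(m$benzene, "rA", 0L))
  lig <- m$phenol; lig$id <- "L1"
  t1 <- target_record("T1", "1AAA", list(lig))
  sc <- tr_scorer("failing", function(...) stop("engine crashed"))
  sm <- dock_all(rings, list(t1), sc, seed = 5)
  expect_true(is.na(sm$scores["T1", "rA"]))
  expect_match(sm$failures$reason[1], "engine crashed")
})

test_that("heatmap export writes a byte-stable CSV next to the image", {
  m <- named_matrix(sample(1:20), 4, 5)
  rr <- rank_transform(-m, "rows")
  p1 <- file.path(tempdir(), "hm1"); p2 <- file.path(tempdir(), "hm2")
  export_heatmap(rr, p1)
  export_heatmap(rr, p2)
  expect_identical(readLines(paste0(p1, ".csv")),
                   readLines(paste0(p2, ".csv")))
  got <- utils::read.csv(paste0(p1, ".csv"), row.names = 1)
  expect_equal(as.matrix(got), unclass(rr)[, , drop = FALSE],
               ignore_attr = TRUE)
  expect_true(file.exists(paste0(p1, ".png")))
})
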