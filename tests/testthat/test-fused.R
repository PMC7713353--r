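`%||%` <- function(a, b) if (is.null(a)) b else a

score_rows <- function(tc, tvc = tc, ct = tc) {
  data.frame(tanimoto_combo_norm = tc, ref_tversky_combo_norm = tvc,
             color_tanimoto = ct)
}

test_that("pair aggregation computes the documented statistics", {
  st <- aggregate_pair(score_rows(1), "r", "t")
  expect_equal(st$tanimoto_combo_max, 1)
  expect_equal(st$tanimoto_combo_mean, 1)
  expect_equal(st$ref_tversky_combo_min, 1)
  expect_equal(st$count, 1L)

  st2 <- aggregate_pair(score_rows(c(0.4, 0.8)))
  expect_equal(st2$tanimoto_combo_mean, 0.6)
  expect_equal(st2$tanimoto_combo_max, 0.8)
  expect_true(st2$ref_tversky_combo_min <= st2$ref_tversky_combo_mean)
  expect_true(st2$ref_tversky_combo_mean <= st2$ref_tversky_combo_max)
})

test_that("the retention cap and cutoff govern the count", {
  set.seed(3)
  many <- score_rows(runif(600))
  st <- aggregate_pair(many)
  expect_equal(st$count, 500L)
  # the cap keeps the top comparisons by combo score
  expect_equal(st$tanimoto_combo_max, max(many$tanimoto_combo_norm))
  expect_gte(st$tanimoto_combo_min %||% st$ref_tversky_combo_min,
             sort(many$tanimoto_combo_norm, decreasing = TRUE)[600 - 99])
  # everything below the cutoff is dropped; an empty pair is unscored
  expect_null(aggregate_pair(score_rows(numeric())))
  expect_null(aggregate_pair(score_rows(c(-0.5, -0.2)), cutoff = -0.1))
})

test_that("the fused score is the exact product of its seven factors", {
  st <- aggregate_pair(score_rows(1))
  expect_equal(fused_score(st)$value, 1)

  st2 <- data.frame(ref_tversky_combo_max = 0.8, tanimoto_combo_mean = 0.6,
                    ref_tversky_combo_mean = 0.7, tanimoto_combo_max = 0.75,
                    ref_tversky_combo_min = 0.5, color_tanimoto_min = 0.4,
                    count = 3)
  expect_equal(fused_score(st2)$value, 0.1512)

  # a ring-free comparison annihilates the product through the color term
  st3 <- st2; st3$color_tanimoto_min <- 0
  expect_equal(fused_score(st3)$value, 0)
})

test_that("zero-annihilation and multiplicative scaling hold on random tuples", {
  set.seed(77)
  fields <- c("ref_tversky_combo_max", "tanimoto_combo_mean",
              "ref_tversky_combo_mean", "tanimoto_combo_max",
              "ref_tversky_combo_min", "color_tanimoto_min", "count")
  for (k in seq_len(1000)) {
    vals <- c(runif(6), sample(1:500, 1))
    zero_one <- sample(c(TRUE, FALSE), 1)
    if (zero_one) vals[sample(1:6, 1)] <- 0
    st <- as.data.frame(as.list(stats::setNames(vals, fields)))
    fs <- fused_score(st)
    expect_equal(fs$value, prod(vals))
    expect_identical(fs$value == 0, any(vals == 0))
    # scaling any single factor by lambda scales the product by lambda
    lam <- runif(1, 0.1, 3); pick <- sample(1:7, 1)
    st2 <- st; st2[[fields[pick]]] <- st2[[fields[pick]]] * lam
    expect_equal(fused_score(st2)$value, fs$value * lam,
                 tolerance = 1e-12)
  }
})

test_that("best lists equal a brute-force argmax oracle", {
  set.seed(41)
  rings <- sprintf("r%d", 1:5); targets <- sprintf("t%d", 1:4)
  pairs <- expand.grid(ring_id = rings, target_id = targets,
                       stringsAsFactors = FALSE)
  pairs$fused <- runif(nrow(pairs))
  pairs$fused[sample(nrow(pairs), 3)] <- NA  # unscored pairs
  bl <- best_lists(pairs)
  for (r in rings) {
    sub <- pairs[pairs$ring_id == r & !is.na(pairs$fused), ]
    want <- sub$target_id[which.max(sub$fused)]
    got <- bl$best_target_per_ring$target_id[
      bl$best_target_per_ring$ring_id == r]
    expect_equal(got, want)
  }
  for (t in targets) {
    sub <- pairs[pairs$target_id == t & !is.na(pairs$fused), ]
    want <- sub$ring_id[which.max(sub$fused)]
    expect_equal(bl$best_ring_per_target$ring_id[
      bl$best_ring_per_target$target_id == t], want)
  }
})

test_that("an axis with only unscored pairs is flagged, never assigned", {
  pairs <- data.frame(ring_id = c("r1", "r1", "r2", "r2"),
                      target_id = c("t1", "t2", "t1", "t2"),
                      fused = c(0.5, 0.2, NA, NA))
  bl <- best_lists(pairs)
  row <- bl$best_target_per_ring[bl$best_target_per_ring$ring_id == "r2", ]
  expect_true(is.na(row$target_id))
  expect_equal(row$flag, "no similar target")
  # unscored pairs never win even when their axis has scored entries
  expect_equal(bl$best_ring_per_target$ring_id,
               c("r1", "r1"))
})

test_that("best lists are invariant under monotone transforms", {
  set.seed(13)
  pairs <- expand.grid(ring_id = sprintf("r%d", 1:4),
                       target_id = sprintf("t%d", 1:4),
                       stringsAsFactors = FALSE)
  pairs$fused <- runif(nrow(pairs))
  bl1 <- best_lists(pairs)
  pairs2 <- pairs; pairs2$fused <- exp(3 * pairs2$fused) - 0.5
  bl2 <- best_lists(pairs2)
  expect_equal(bl1$best_target_per_ring$target_id,
               bl2$best_target_per_ring$target_id)
  expect_equal(bl1$best_ring_per_target$ring_id,
               bl2$best_ring_per_target$ring_id)
})
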