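test_that("inclusion mask applies the floor(coverage * n) rule with an intact guard", {
  g <- tiny_grid(c(6L, 6L, 4L))
  # 10 subjects: voxel (2,2,2) lesioned in 2, voxel (3,3,3) in 1,
  # voxel (4,4,4) in 9 of 10 (only 1 intact -> excluded)
  lists <- lapply(1:10, function(i) {
    rows <- NULL
    if (i <= 2) rows <- rbind(rows, c(2, 2, 2))
    if (i == 1) rows <- rbind(rows, c(3, 3, 3))
    if (i <= 9) rows <- rbind(rows, c(4, 4, 4))
    if (is.null(rows)) rows <- matrix(numeric(0), 0, 3)
    rows
  })
  co <- tiny_cohort(g, lists, scores = round(seq(10, 60, length.out = 10)))
  inc <- inclusion_mask(co, 0.20)
  expect_equal(inc$min_lesioned, 2L)           # floor(0.2 * 10)
  expect_true(inc$mask[2, 2, 2])
  expect_false(inc$mask[3, 3, 3])              # below coverage
  expect_false(inc$mask[4, 4, 4])              # only one intact subject
  expect_error(inclusion_mask(co, 1.2), "coverage")
  # the cohort-scale anchor: 20% of 41 subjects floors to 8
  expect_equal(floor(0.20 * 41), 8)
})

test_that("voxel_test matches the exhaustive permutation oracle", {
  # canonical example: complete separation of 3 vs 3
  or <- perm_rank_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(or$p, 0.05)  # 1 of choose(6,3) = 20 assignments
  vt <- voxel_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(vt$U, or$U)
  expect_equal(vt$z, 4.5 / sqrt(5.25), tolerance = 1e-12)
  expect_equal(vt$z, 1.9640, tolerance = 1e-4)
  expect_lt(abs(vt$p - or$p), 0.03)

  # rank-sum statistic matches enumeration exactly for all splits at n <= 10,
  # ties included
  set.seed(7)
  for (N in c(5L, 7L, 10L)) {
    scores <- sample(1:6, N, replace = TRUE)  # ordinal with ties
    for (n1 in 1:(N - 1L)) {
      les <- scores[seq_len(n1)]
      int <- scores[-seq_len(n1)]
      expect_identical(voxel_test(les, int)$U, perm_rank_oracle(les, int)$U)
    }
  }
  # the normal approximation targets the mid-p of the discrete permutation
  # distribution; on untied data with both groups >= 2 it stays within 0.03
  set.seed(8)
  for (N in c(6L, 8L, 10L)) {
    scores <- sample(100, N)
    for (n1 in 2:(N - 2L)) {
      les <- scores[seq_len(n1)]
      int <- scores[-seq_len(n1)]
      expect_lt(abs(voxel_test(les, int)$p - perm_rank_oracle(les, int)$p_mid),
                0.03)
    }
  }
})

test_that("voxel_test sign convention, antisymmetry and degenerate ties", {
  # z > 0 when the lesioned group scores worse (lower)
  expect_gt(voxel_test(c(1, 2, 3), c(4, 5, 6))$z, 0)
  expect_lt(voxel_test(c(4, 5, 6), c(1, 2, 3))$z, 0)
  a <- c(12, 3, 7, 9)
  b <- c(15, 2, 8)
  expect_equal(voxel_test(a, b)$z, -voxel_test(b, a)$z, tolerance = 1e-12)
  # all observations identical: no signal, not an error
  d <- voxel_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(d$z, 0)
  expect_equal(d$p, 0.5)
  expect_error(voxel_test(numeric(0), c(1, 2)), "non-empty")
})

test_that("map_scores composes voxel_test and keeps z/p consistent", {
  g <- tiny_grid(c(6L, 6L, 4L))
  # single included voxel lesioned in subjects 1-3 of 6
  lists <- lapply(1:6, function(i) {
    if (i <= 3) rbind(c(2, 2, 2)) else matrix(numeric(0), 0, 3)
  })
  co <- tiny_cohort(g, lists, scores = c(1, 2, 3, 4, 5, 6))
  inc <- array(FALSE, g$dims)
  inc[2, 2, 2] <- TRUE
  res <- map_scores(co, "FMA_UL", inc)
  vt <- voxel_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$z[2, 2, 2], vt$z)
  expect_equal(res$p[2, 2, 2], vt$p)
  expect_true(is.na(res$z[1, 1, 1]))
  # z/p are order-inverses through the normal tail at every tested voxel
  co2 <- bernoulli_cohort(n = 21L, dims = c(6L, 6L, 4L), seed = 3)
  inc2 <- inclusion_mask(co2, 0.20)
  res2 <- map_scores(co2, "FMA_UL", inc2)
  vox <- which(inc2$mask)
  expect_equal(res2$p[vox], pnorm(res2$z[vox], lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(map_scores(co, "FMA_UL", array(FALSE, g$dims)), "no voxels")
})

test_that("type-I error of the voxel test is near nominal under the null", {
  co <- bernoulli_cohort(n = 41L, dims = c(10L, 10L, 5L), seed = 11)
  inc <- array(TRUE, co$grid$dims)  # all 500 voxels
  res <- map_scores(co, "FMA_UL", inc)
  frac <- mean(res$p < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / 500)
  expect_gt(frac, 0.05 - bound)
  expect_lt(frac, 0.05 + bound)
})

test_that("fdr_select implements BH step-up and records realized thresholds", {
  g <- tiny_grid(c(4L, 1L, 1L))
  res <- structure(list(
    score_name = "FMA_UL", inclusion = array(TRUE, g$dims),
    z = array(qnorm(c(0.01, 0.02, 0.03, 0.5), lower.tail = FALSE), g$dims),
    p = array(c(0.01, 0.02, 0.03, 0.5), g$dims),
    sig = NULL, threshold_info = NULL, min_lesioned = 2L, grid = g, n = 10L),
    class = "vlsm_result")
  out <- fdr_select(res, q = 0.05)
  expect_equal(as.vector(out$sig), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$threshold_info$p_star, 0.03)
  expect_equal(out$threshold_info$z_star,
               qnorm(0.03, lower.tail = FALSE))
  # all p = 1 -> nothing rejected
  res1 <- res
  res1$p[] <- 1
  expect_equal(sum(fdr_select(res1)$sig), 0L)
  # monotonicity in q
  set.seed(5)
  res$p[] <- runif(4)
  expect_true(all(which(fdr_select(res, 0.01)$sig) %in%
                    which(fdr_select(res, 0.05)$sig)))
})

test_that("BH rejection sets match the brute-force step-up oracle", {
  set.seed(19)
  g <- tiny_grid(c(25L, 2L, 1L))
  for (rep in 1:200) {
    p <- runif(50)^sample(c(1, 2, 3), 1)  # varying signal density
    res <- structure(list(
      score_name = "s", inclusion = array(TRUE, g$dims),
      z = array(qnorm(p, lower.tail = FALSE), g$dims), p = array(p, g$dims),
      sig = NULL, threshold_info = NULL, min_lesioned = 2L, grid = g, n = 10L),
      class = "vlsm_result")
    expect_identical(as.vector(fdr_select(res, 0.05)$sig), bh_oracle(p, 0.05))
  }
})

test_that("lenient selection thresholds z and derives from an FDR reference", {
  g <- tiny_grid(c(4L, 1L, 1L))
  z <- c(2.5, 2.09, 1.9, 3.5)
  res <- structure(list(
    score_name = "s", inclusion = array(TRUE, g$dims),
    z = array(z, g$dims), p = array(pnorm(z, lower.tail = FALSE), g$dims),
    sig = NULL, threshold_info = NULL, min_lesioned = 2L, grid = g, n = 10L),
    class = "vlsm_result")
  out <- lenient_select(res, 2.09)
  expect_equal(as.vector(out$sig), c(TRUE, TRUE, FALSE, TRUE))
  # the quoted threshold correspondence: z >= 2.09 means one-sided p <= 0.0183
  expect_true(all(res$p[out$sig] <= 0.0184))
  expect_equal(sum(lenient_select(res, Inf)$sig), 0L)
  expect_equal(sum(lenient_select(res, -Inf)$sig), sum(res$inclusion))
  # derived threshold is the minimum significant z of the reference
  ref <- lenient_select(res, 2.09)
  expect_equal(derive_lenient_threshold(ref), 2.09)
  one <- lenient_select(res, 3.4)
  expect_equal(derive_lenient_threshold(one), 3.5)
  # adding a larger-z voxel leaves the minimum unchanged
  res2 <- res
  res2$z[3] <- 4
  expect_equal(derive_lenient_threshold(lenient_select(res2, 2.09)), 2.09)
  empty <- lenient_select(res, Inf)
  expect_error(derive_lenient_threshold(empty), "no significant")
})

test_that("FDR at its realized cutoff never exceeds the matched lenient set", {
  set.seed(23)
  g <- tiny_grid(c(20L, 2L, 1L))
  p <- runif(40)^2
  res <- structure(list(
    score_name = "s", inclusion = array(TRUE, g$dims),
    z = array(qnorm(p, lower.tail = FALSE), g$dims), p = array(p, g$dims),
    sig = NULL, threshold_info = NULL, min_lesioned = 2L, grid = g, n = 10L),
    class = "vlsm_result")
  fdr <- fdr_select(res, 0.05)
  len <- lenient_select(res, fdr$threshold_info$z_star)
  expect_true(all(which(fdr$sig) %in% which(len$sig)))
})
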