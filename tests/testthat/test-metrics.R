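test_that("Hausdorff-family distances reproduce the hand-worked cases", {
  A <- rbind(c(0, 0), c(3, 0))
  B <- rbind(c(0, 0))
  expect_equal(directed_hausdorff(A, B), 3)
  expect_equal(directed_hausdorff(B, A), 0)
  expect_equal(hausdorff(A, B), 3)
  expect_equal(hausdorff(A, A), 0)
  A2 <- rbind(c(0, 0), c(1, 0))
  m <- modified_hausdorff(A2, B)
  expect_equal(as.numeric(m), 0.5)
  expect_equal(unname(attr(m, "directed")), c(0.5, 0))
  expect_equal(as.numeric(modified_hausdorff(A2, A2)), 0)
  expect_error(directed_hausdorff(A[0, , drop = FALSE], B), "empty")
})

test_that("metrics match the O(nm) brute-force oracles on random sets", {
  set.seed(7)
  for (rep in 1:100) {
    nd <- sample(2:3, 1)
    A <- matrix(runif(sample(1:50, 1) * nd, -10, 10), ncol = nd)
    B <- matrix(runif(sample(1:50, 1) * nd, -10, 10), ncol = nd)
    dh <- oracle_directed_hausdorff(A, B)
    dhr <- oracle_directed_hausdorff(B, A)
    expect_equal(directed_hausdorff(A, B), dh)
    expect_equal(hausdorff(A, B), max(dh, dhr))
    mh <- modified_hausdorff(A, B)
    expect_equal(as.numeric(mh),
                 max(oracle_directed_mhd(A, B), oracle_directed_mhd(B, A)))
    expect_lte(as.numeric(mh), hausdorff(A, B))  # mean <= max
  }
})

test_that("metrics are symmetric, nonnegative and translation-equivariant", {
  set.seed(11)
  for (rep in 1:20) {
    A <- matrix(runif(40), ncol = 2)
    B <- matrix(runif(30), ncol = 2)
    expect_equal(hausdorff(A, B), hausdorff(B, A))
    expect_equal(as.numeric(modified_hausdorff(A, B)),
                 as.numeric(modified_hausdorff(B, A)))
    expect_gte(directed_hausdorff(A, B), 0)
    t <- runif(2, -5, 5)
    At <- sweep(A, 2, t, "+"); Bt <- sweep(B, 2, t, "+")
    expect_equal(hausdorff(At, Bt), hausdorff(A, B), tolerance = 1e-12)
    expect_equal(as.numeric(modified_hausdorff(At, Bt)),
                 as.numeric(modified_hausdorff(A, B)), tolerance = 1e-12)
  }
})

test_that("spacing converts voxel distances to millimetres", {
  A <- rbind(c(0, 0), c(1, 0))
  B <- rbind(c(0, 0))
  expect_equal(directed_hausdorff(A, B, spacing = c(4.25, 1)), 4.25)
})

test_that("isocontour feature points of a binary square are its perimeter", {
  img <- matrix(0, 12, 12)
  img[4:9, 5:8] <- 1
  pts <- extract_feature_points(scalar_image(img), "isocontour",
                                threshold = 0.5)
  perim <- NULL
  for (i in 4:9) for (j in 5:8) {
    if (i %in% c(4, 9) || j %in% c(5, 8)) perim <- rbind(perim, c(i, j))
  }
  expect_equal(pts[order(pts[, 1], pts[, 2]), ],
               perim[order(perim[, 1], perim[, 2]), ])
})

test_that("isocontour keeps only the largest connected component", {
  img <- matrix(0, 16, 16)
  img[3:10, 3:10] <- 1   # 8x8 block
  img[13:14, 13:14] <- 1 # small distractor
  pts <- extract_feature_points(scalar_image(img), "isocontour",
                                threshold = 0.5)
  expect_true(all(pts[, 1] <= 10 & pts[, 2] <= 10))
})

test_that("feature extraction errors on featureless input", {
  expect_error(
    extract_feature_points(scalar_image(matrix(0.5, 8, 8)), "isocontour",
                           threshold = 0.9),
    "threshold")
})

test_that("feature points of a 1-voxel-shifted image stay within M-HD 1", {
  set.seed(3)
  base <- matrix(0, 20, 20)
  base[6:14, 5:15] <- 1
  shifted <- matrix(0, 20, 20)
  shifted[7:15, 5:15] <- 1
  A <- extract_feature_points(scalar_image(base), "isocontour", 0.5)
  B <- extract_feature_points(scalar_image(shifted), "isocontour", 0.5)
  expect_lte(as.numeric(modified_hausdorff(A, B)), 1)
})

test_that("edge method finds the contour of a smooth step", {
  x <- matrix(rep(1:24, 24), 24, 24)
  img <- scalar_image(gmidemons:::.gaussian_smooth_array(
    (x > 12) * 1.0, 1.5))
  pts <- extract_feature_points(img, "edge", threshold = 0.5)
  expect_true(all(abs(pts[, 1] - 12.5) < 3))
})
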