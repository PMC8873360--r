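test_that("pca_transform centres, diagonalizes and preserves distances", {
  pc <- box_cloud(c(8, 3, 2), n = 3000)
  out <- pca_transform(pc)
  q <- out$cloud$points
  expect_lt(max(abs(colMeans(q))), 1e-9)
  cv <- crossprod(q) / nrow(q)
  expect_lt(max(abs(cv[upper.tri(cv)])) / sum(diag(cv)), 1e-9)
  expect_equal(out$cloud$frame, "pca")

  # isometry on a subsample
  idx <- seq(1, 3000, by = 150)
  d0 <- dist(pc$points[idx, ])
  d1 <- dist(q[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)

  # rotation is proper and orthonormal
  r <- out$transform$rotation
  expect_lt(max(abs(r %*% t(r) - diag(3))), 1e-9)
  expect_equal(det(r), 1, tolerance = 1e-12)

  # inverse transform restores the input
  back <- apply_transform(out$transform, q, inverse = TRUE)
  expect_lt(max(abs(back - pc$points)), 1e-9)
})

test_that("pca_transform recovers the symmetry axis of collinear points", {
  t <- seq(0, 1, length.out = 50)
  pc <- point_cloud(cbind(10 * t, 10 * t, 0))
  out <- pca_transform(pc)
  e1 <- out$transform$rotation[1, ]
  expect_lt(min(max(abs(e1 - c(1, 1, 0) / sqrt(2))),
                max(abs(e1 + c(1, 1, 0) / sqrt(2)))), 1e-9)
  expect_error(pca_transform(point_cloud(rbind(c(1, 1, 1)))), "at least 3")
  expect_error(pca_transform(point_cloud(matrix(1, 5, 3))), "covariance")
})

test_that("pca_transform maps a rotated box back to its extents", {
  pc <- box_cloud(c(8, 3, 2), n = 6000)
  r <- rot3(c(1, -2, 0.5), 1.1)
  rot_pc <- point_cloud(pc$points %*% t(r) + 5)
  out <- pca_transform(rot_pc)
  ext <- sort(apply(out$cloud$points, 2, function(v) diff(range(v))),
              decreasing = TRUE)
  expect_lt(max(abs(ext - c(8, 3, 2)) / c(8, 3, 2)), 0.02)
})

test_that("voxel_downsample averages per voxel and is idempotent on grids", {
  corners <- as.matrix(expand.grid(c(0.1, 0.9), c(0.1, 0.9), c(0.1, 0.9)))
  pc <- point_cloud(corners)
  one <- voxel_downsample(pc, 2)
  expect_equal(n_points(one), 1)
  expect_equal(as.numeric(one$points), c(0.5, 0.5, 0.5))

  # leaf below the minimum pairwise distance: identity up to order
  g <- grid_cloud(5, by = 1)
  same <- voxel_downsample(g, 0.5)
  expect_equal(n_points(same), 25)
  expect_equal(g$points[order(g$points[, 1], g$points[, 2]), ],
               same$points[order(same$points[, 1], same$points[, 2]), ])

  # two clusters 10 mm apart stay separate and keep their means when each
  # cluster fits inside a single voxel
  withr::with_seed(3, {
    cl <- rbind(matrix(rnorm(60, mean = 1, sd = 0.2), ncol = 3),
                matrix(rnorm(60, mean = 11, sd = 0.2), ncol = 3))
  })
  ds <- voxel_downsample(point_cloud(cl), 4)
  expect_equal(n_points(ds), 2)
  lab <- ds$points[, 1] > 5
  expect_lt(max(abs(ds$points[!lab, ] - colMeans(cl[1:20, ]))), 1e-9)
  expect_lt(max(abs(ds$points[lab, ] - colMeans(cl[21:40, ]))), 1e-9)

  # idempotence on the grid fixture
  again <- voxel_downsample(same, 0.5)
  expect_equal(n_points(again), n_points(same))

  expect_error(voxel_downsample(g, 0), "positive")
})

test_that("voxel means equal brute-force per-voxel means", {
  withr::with_seed(5, {
    p <- matrix(runif(600, 0, 7), ncol = 3)
  })
  leaf <- 1.3
  ds <- voxel_downsample(point_cloud(p), leaf)
  key <- paste(floor(p[, 1] / leaf), floor(p[, 2] / leaf), floor(p[, 3] / leaf))
  ref <- do.call(rbind, lapply(split(seq_len(nrow(p)), key), function(i) {
    colMeans(p[i, , drop = FALSE])
  }))
  ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), ]
  expect_equal(ord(ds$points), ord(ref), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lte(n_points(ds), nrow(p))
})

test_that("statistical filter removes exactly the isolated point", {
  g <- grid_cloud(10, by = 1)
  pc <- point_cloud(rbind(g$points, c(100, 100, 0)))
  out <- statistical_outlier_filter(pc, k = 8, std_mult = 1)
  expect_equal(n_points(out), 100)
  expect_true(all(out$points[, 1] <= 10))

  # loose threshold removes nothing
  all_kept <- statistical_outlier_filter(pc, k = 8, std_mult = 10)
  expect_equal(n_points(all_kept), 101)

  # output is a subset: no coordinate is modified
  match_rows <- FNN::get.knnx(pc$points, out$points, k = 1)$nn.dist[, 1]
  expect_lt(max(match_rows), 1e-12)

  expect_error(statistical_outlier_filter(g, k = 100), "more than k")
})

test_that("statistical filter removes under 1% of homogeneous data at 3 sigma", {
  # a closed surface sample has no boundary shell, so the neighbour
  # distances are genuinely homogeneous
  sp <- make_sphere_cloud(10, 3000, 0, seed = 8)
  out <- statistical_outlier_filter(sp, k = 20, std_mult = 3)
  expect_gt(n_points(out), 0.99 * 3000)
})
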