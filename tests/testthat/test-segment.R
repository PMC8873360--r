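test_that("normal estimation matches analytic normals and bounds curvature", {
  # planar patch: normals along z, curvature ~ 0
  g <- grid_cloud(15, by = 0.5)
  gn <- estimate_normals(g, k = 10)
  expect_lt(max(acos(pmin(1, abs(gn$normals[, 3])))) * 180 / pi, 1)
  expect_lt(max(gn$curvature), 1e-6)

  # sphere: normals track the radial direction (worst neighbourhoods are
  # elongated Poisson clusters, hence the looser tail bound)
  sp <- sphere_cloud(8000, r = 10, seed = 2)
  sn <- estimate_normals(sp, k = 15)
  ang <- acos(pmin(1, abs(rowSums(sn$normals * sp$points / 10)))) * 180 / pi
  expect_lt(stats::quantile(ang, 0.99), 2)
  expect_lt(max(ang), 5)

  # curvature is a ratio of eigenvalues, always in [0, 1/3]
  expect_true(all(sn$curvature >= 0 & sn$curvature <= 1 / 3 + 1e-12))

  # outward orientation
  expect_true(all(rowSums(sn$normals * sp$points) > 0))

  expect_error(estimate_normals(g, k = 1000), "more than k")
})

test_that("RANSAC recovers a plane among outliers and is seed-stable", {
  withr::with_seed(4, {
    inl <- cbind(runif(900, -20, 20), runif(900, -20, 20), rnorm(900, 0, 0.02))
    out <- cbind(runif(100, -20, 20), runif(100, -20, 20), runif(100, 1, 30))
  })
  pc <- point_cloud(rbind(inl, out))
  pl <- fit_plane_ransac(pc, dist_mm = 0.1, iters = 100, seed = 1)
  expect_lt(acos(min(1, abs(pl$normal[3]))) * 180 / pi, 0.5)
  expect_lt(abs(pl$offset_mm), 0.05)
  expect_gt(length(pl$inlier_indices), 850)

  # bit-reproducible under a fixed seed
  pl2 <- fit_plane_ransac(pc, dist_mm = 0.1, iters = 100, seed = 1)
  expect_identical(pl$normal, pl2$normal)
  expect_identical(pl$inlier_indices, pl2$inlier_indices)

  # exact plane: every point is an inlier
  flat <- grid_cloud(10, by = 1, z = 3)
  plf <- fit_plane_ransac(flat, 0.1, 50, seed = 2)
  expect_length(plf$inlier_indices, 100)
  expect_equal(abs(plf$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(plf$offset_mm, 3, tolerance = 1e-9)

  # three non-collinear points: interpolating plane
  tri <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 1), c(0, 1, 1)))
  plt <- fit_plane_ransac(tri, 0.01, 20, seed = 3)
  expect_lt(max(abs(tri$points %*% plt$normal - plt$offset_mm)), 1e-9)
})

test_that("remove_plane keeps the grain side beyond the margin", {
  withr::with_seed(6, {
    plane <- cbind(runif(2000, -30, 30), runif(2000, -30, 30), rnorm(2000, 0, 0.03))
    blob <- sweep(matrix(rnorm(900, sd = 0.8), ncol = 3), 2, c(0, 0, 5), `+`)
  })
  pc <- point_cloud(rbind(plane, blob))
  pl <- fit_plane_ransac(pc, 0.2, 100, seed = 1)
  kept <- remove_plane(pc, pl, margin_mm = 0.5)
  s <- kept$points %*% pl$normal - pl$offset_mm
  expect_true(all(abs(s) > 0.5))          # margin contract
  expect_gt(n_points(kept), 290)          # the 300-point blob survives
  expect_lt(n_points(kept), 320)          # the plane does not

  # plane-only cloud: empty output with a warning, not an error
  flat <- grid_cloud(12, by = 1)
  plf <- fit_plane_ransac(flat, 0.1, 50, seed = 1)
  expect_warning(empty <- remove_plane(flat, plf, 0.5), "no points")
  expect_equal(n_points(empty), 0)
})

test_that("region growing separates disconnected spheres and honours size limits", {
  s1 <- sphere_cloud(1500, r = 5, seed = 1)
  s2 <- sphere_cloud(1500, r = 5, seed = 2)
  p2 <- s2$points
  p2[, 1] <- p2[, 1] + 20
  both <- estimate_normals(point_cloud(rbind(s1$points, p2)), k = 15)
  segs <- region_growing(both, min_pts = 100, max_pts = 10000, k = 15)
  expect_length(segs, 2)
  sizes <- sort(vapply(segs, function(s) n_points(s$cloud), integer(1)))
  expect_equal(sum(sizes), 3000)
  # each segment holds exactly one sphere's points
  cx <- vapply(segs, function(s) s$centroid[1], numeric(1))
  expect_equal(sort(round(cx)), c(0, 20))

  # min_pts above the largest cluster: empty result with a warning
  expect_warning(none <- region_growing(both, min_pts = 5000, max_pts = 10000,
                                        k = 15), "size range")
  expect_length(none, 0)

  expect_error(region_growing(point_cloud(s1$points)), "normals")
})

test_that("grid cell assignment is injective and reports collisions", {
  lay <- grid_layout(2, 3, 1, spacing_mm = 20)
  segs <- lapply(seq_len(7), function(i) {
    structure(list(grain_id = i,
                   cloud = point_cloud(matrix(rnorm(9), ncol = 3)),
                   centroid = c(lay$centers[i, ] + c(0.5, -0.3), 4),
                   grid_cell = NULL), class = "grain_segment")
  })
  out <- assign_grid_cells(segs, lay)
  cells <- t(vapply(out, function(s) s$grid_cell, numeric(2)))
  expect_equal(nrow(unique(cells)), 7)
  expect_equal(out[[7]]$grid_cell[1], 0)  # extra cell row tag

  # single segment: nearest cell
  one <- assign_grid_cells(segs[3], lay)
  expect_equal(one[[1]]$grid_cell, c(lay$cell$row[3], lay$cell$col[3]))

  # two segments nearest to the same cell -> collision error naming both
  segs[[2]]$centroid <- segs[[1]]$centroid + c(0.2, 0.2, 0)
  expect_error(assign_grid_cells(segs, lay), "collision")

  # more segments than cells -> pigeonhole error
  expect_error(assign_grid_cells(c(segs, segs), lay), "injectively")
})
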