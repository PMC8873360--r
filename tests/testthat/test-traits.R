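test_that("oriented bounding box recovers rotated box extents", {
  pc <- box_cloud(c(8, 3, 2), n = 8000)
  r <- rot3(c(0.3, 1, -2), 0.8)
  rotated <- point_cloud(sweep(pc$points %*% t(r), 2, c(4, -7, 2), `+`))
  ob <- oriented_bbox(rotated)
  expect_equal(unname(ob$box$extents), c(8, 3, 2), tolerance = 0.02)
  expect_true(all(diff(ob$box$extents) <= 1e-12))  # l >= w >= h

  # rigid-motion invariance of the extents
  ob0 <- oriented_bbox(pc)
  expect_equal(unname(ob$box$extents), unname(ob0$box$extents),
               tolerance = 1e-6)

  # sphere: all three extents agree with the diameter
  sp <- sphere_cloud(6000, r = 10, seed = 6)
  obs <- oriented_bbox(sp)
  expect_equal(unname(obs$box$extents), c(20, 20, 20), tolerance = 0.2)

  expect_error(oriented_bbox(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0),
                                               c(2, 0, 0), c(3, 0, 0)))),
               "degenerate")
})

test_that("planar projections recover analytic disc area and perimeter", {
  sp <- sphere_cloud(20000, r = 10, seed = 1)
  ob <- oriented_bbox(sp)
  prs <- lapply(c("cross", "longitudinal", "horizontal"),
                function(s) project_section(ob$cloud, s))
  areas <- vapply(prs, function(p) p$area_mm2, numeric(1))
  perims <- vapply(prs, function(p) p$perimeter_mm, numeric(1))
  expect_lt(max(abs(areas - 100 * pi) / (100 * pi)), 0.02)
  expect_lt(max(abs(perims - 20 * pi) / (20 * pi)), 0.02)
  # the three sections of a sphere agree with each other
  expect_lt(diff(range(areas)) / mean(areas), 0.01)

  # dense in-plane unit square: area 1, perimeter 4
  g <- expand.grid(x = seq(0, 1, by = 0.02), y = seq(0, 1, by = 0.02))
  sq <- point_cloud(cbind(g$x, g$y, 0), frame = "obb")
  pr <- project_section(sq, "horizontal")
  expect_equal(pr$area_mm2, 1, tolerance = 0.02)
  expect_equal(pr$perimeter_mm, 4, tolerance = 0.02)

  expect_error(project_section(point_cloud(rbind(c(0, 0, 0))), "cross"),
               "degenerate")
})

test_that("compactness matches closed forms and the isoperimetric floor", {
  expect_equal(compactness(2 * pi * 3, pi * 9), 1)
  expect_equal(compactness(4, 1), 4 / pi)
  expect_equal(compactness(6, 2), 36 / (8 * pi))
  expect_error(compactness(0, 1), "positive")
  expect_error(compactness(1, -2), "positive")
})

test_that("full trait vectors are internally consistent and accurate on solids", {
  # noise-free ellipsoid grain: volume within 2% of (4/3) pi a b c
  gc <- make_grain_cloud(grain_spec(8, 3, 2), 35, 0, seed = 4)
  tv <- compute_traits(gc)
  tr <- tv$traits
  expect_equal(unname(tr["V"]), 4 / 3 * pi * 4 * 1.5 * 1, tolerance = 0.02)
  expect_equal(unname(tr[c("l", "w", "h")]), c(8, 3, 2), tolerance = 0.02)
  # cross section of the ellipsoid: ellipse (1.5, 1)
  expect_equal(unname(tr["S_yz"]), pi * 1.5, tolerance = 0.02)

  # algebraic identities hold to machine precision
  expect_equal(unname(tr["V_obb"]), unname(tr["l"] * tr["w"] * tr["h"]),
               tolerance = 1e-9)
  expect_equal(unname(tr["S_V"] * tr["V_l"]), unname(tr["S_l"]),
               tolerance = 1e-9)
  expect_equal(unname(tr["l_w"] * tr["w_h"]), unname(tr["l_h"]),
               tolerance = 1e-9)
  expect_equal(unname(tr["c_yz"]),
               unname(tr["C_yz"]^2 / (4 * pi * tr["S_yz"])), tolerance = 1e-9)
  expect_true(all(tr > 0))
  expect_lt(unname(tr["V"]), unname(tr["V_obb"]))
})

test_that("synthetic sphere grain reproduces the validation-grade accuracy", {
  sp <- make_sphere_cloud(10, 25000, 0, seed = 2)
  tv <- compute_traits(point_cloud(sp$points, sp$normals))
  tr <- tv$traits
  expect_equal(unname(tr[c("l", "w", "h")]), c(20, 20, 20), tolerance = 0.01)
  expect_lt(abs(tr["S"] - 400 * pi) / (400 * pi), 0.0283)
  expect_lt(abs(tr["V"] - 4000 * pi / 3) / (4000 * pi / 3), 0.0175)
  expect_lt(max(abs(tr[c("c_yz", "c_xz", "c_xy")] - 1)), 0.05)
})

test_that("traits scale with the expected powers of a spatial rescale", {
  gc <- make_grain_cloud(grain_spec(8, 3, 2), 20, 0, seed = 6)
  t1 <- compute_traits(gc)$traits
  s <- 2
  t2 <- compute_traits(point_cloud(gc$points * s, gc$normals))$traits
  lengths <- c("l", "w", "h", "C_yz", "C_xz", "C_xy")
  areas <- c("S", "S_yz", "S_xz", "S_xy")
  expect_equal(unname(t2[lengths] / t1[lengths]), rep(s, 6), tolerance = 1e-6)
  expect_equal(unname(t2[areas] / t1[areas]), rep(s^2, 4), tolerance = 1e-6)
  expect_equal(unname(t2["V"] / t1["V"]), s^3, tolerance = 1e-6)
  expect_equal(unname(t2[c("l_w", "l_h", "w_h")]),
               unname(t1[c("l_w", "l_h", "w_h")]), tolerance = 1e-6)
})
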