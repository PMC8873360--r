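test_that("Heron-sum area is exact on closed-form fixtures", {
  # single 3-4-5 right triangle
  tri <- grain_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), rbind(1:3))
  expect_equal(as.numeric(surface_area(tri)), 6)
  # unit cube: 12 triangles, total 6
  expect_equal(as.numeric(surface_area(cube_mesh())), 6)
  # rigid-motion invariance and additivity over face subsets
  cm <- cube_mesh()
  r <- rot3(c(2, 1, 3), 0.9)
  moved <- grain_mesh(cm$vertices %*% t(r) + 2, cm$faces)
  expect_equal(as.numeric(surface_area(moved)), 6, tolerance = 1e-12)
  half1 <- grain_mesh(cm$vertices, cm$faces[1:6, ])
  half2 <- grain_mesh(cm$vertices, cm$faces[7:12, ])
  expect_equal(as.numeric(surface_area(half1)) + as.numeric(surface_area(half2)),
               as.numeric(surface_area(cm)))
})

test_that("divergence volume matches closed forms and is rigid-invariant", {
  expect_equal(volume_divergence(cube_mesh()), 1)
  expect_equal(volume_divergence(tetrahedron_mesh(1)), 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  ic <- icosphere_mesh(3, 10)
  r <- rot3(c(1, 1, 1), 2.2)
  moved <- grain_mesh(sweep(ic$vertices %*% t(r), 2, c(5, -3, 11), `+`),
                      ic$faces)
  expect_equal(volume_divergence(moved), volume_divergence(ic),
               tolerance = 1e-9)
  open_mesh <- grain_mesh(cube_mesh()$vertices, cube_mesh()$faces[-1, ])
  expect_error(volume_divergence(open_mesh), "open mesh")
})

test_that("prism volume is exact on the cube and translation-invariant in z", {
  expect_equal(volume_prism(cube_mesh()), 1, tolerance = 1e-9)
  shifted <- grain_mesh(sweep(cube_mesh()$vertices, 2, c(0, 0, 5), `+`),
                        cube_mesh()$faces)
  expect_equal(volume_prism(shifted), 1, tolerance = 1e-9)
  expect_error(volume_prism(grain_mesh(cube_mesh()$vertices,
                                       cube_mesh()$faces[-1, ])), "open mesh")
})

test_that("prism and divergence volumes agree within 0.5% on convex fixtures", {
  fixtures <- list(cube_mesh(2),
                   icosphere_mesh(2, 10), icosphere_mesh(3, 10),
                   icosphere_mesh(4, 10),
                   ellipsoid_mesh(c(4, 1.5, 1), 3))
  for (m in fixtures) {
    vp <- volume_prism(m)
    vd <- volume_divergence(m)
    expect_lt(abs(vp - vd) / vd, 0.005)
  }
  # icosphere subdivision 4 against the analytic ball volume
  expect_lt(abs(volume_prism(icosphere_mesh(4, 10)) - 4000 * pi / 3) /
              (4000 * pi / 3), 0.01)
})

test_that("triangulation meshes the minimal and planar fixtures exactly", {
  # regular tetrahedron with exact outward normals: 4 faces, closed
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / (2 * sqrt(2))
  nrm <- v / sqrt(rowSums(v^2))
  tet <- point_cloud(v, normals = nrm)
  m <- triangulate_surface(tet, radius_mm = 5)
  expect_equal(nrow(m$faces), 4)
  expect_true(is_closed_mesh(m))

  # planar n x n grid -> 2 (n-1)^2 triangles
  g <- grid_cloud(8, by = 1)
  gn <- point_cloud(g$points, normals = matrix(rep(c(0, 0, 1), 64),
                                               ncol = 3, byrow = TRUE))
  gm <- triangulate_surface(gn)
  expect_equal(nrow(gm$faces), 2 * 49)
  expect_equal(as.numeric(surface_area(gm)), 49, tolerance = 1e-6)
})

test_that("sphere samples triangulate to a near-closed accurate surface", {
  sp <- estimate_normals(sphere_cloud(8000, r = 10, seed = 3), k = 20)
  m <- triangulate_surface(sp)
  # boundary edge length below 2% of total edge length
  be <- boundary_edges(m)
  blen <- if (nrow(be) == 0) 0 else
    sum(sqrt(rowSums((m$vertices[be[, 1], , drop = FALSE] -
                        m$vertices[be[, 2], , drop = FALSE])^2)))
  et <- grain3d:::mesh_edge_table(m)
  tot <- sum(sqrt(rowSums((m$vertices[et$a, ] - m$vertices[et$b, ])^2))) / 2
  expect_lt(blen / tot, 0.02)
  expect_gt(attr(m, "coverage"), 0.99)

  closed <- close_mesh(m)
  expect_true(is_closed_mesh(closed))
  expect_equal(euler_characteristic(closed), 2)
  expect_lt(abs(as.numeric(surface_area(closed)) - 400 * pi) / (400 * pi), 0.01)
  expect_lt(abs(volume_divergence(closed) - 4000 * pi / 3) / (4000 * pi / 3), 0.01)
})

test_that("mesh refinement shrinks the sphere area error monotonically", {
  err <- vapply(c(2000, 8000), function(n) {
    sp <- estimate_normals(sphere_cloud(n, r = 10, seed = 5), k = 20)
    m <- close_mesh(triangulate_surface(sp))
    abs(as.numeric(surface_area(m)) - 400 * pi)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("hole filling fans loops, restores the Euler characteristic", {
  ic <- icosphere_mesh(3, 10)
  expect_identical(fill_holes(ic), ic)  # closed mesh: no-op

  # remove a polar cap: every face whose centroid z exceeds 9
  fc <- (ic$vertices[ic$faces[, 1], 3] + ic$vertices[ic$faces[, 2], 3] +
           ic$vertices[ic$faces[, 3], 3]) / 3
  holed <- grain_mesh(ic$vertices, ic$faces[fc < 9, ])
  expect_gt(nrow(boundary_edges(holed)), 0)
  filled <- fill_holes(holed)
  expect_true(is_closed_mesh(filled))
  expect_equal(euler_characteristic(filled), 2)
  # exactly one new vertex for the single cap loop
  expect_equal(nrow(filled$vertices), nrow(ic$vertices) + 1)

  # two caps -> two new vertices
  holed2 <- grain_mesh(ic$vertices, ic$faces[abs(fc) < 9, ])
  filled2 <- fill_holes(holed2)
  expect_true(is_closed_mesh(filled2))
  expect_equal(nrow(filled2$vertices), nrow(ic$vertices) + 2)

  # non-manifold input is rejected
  bad <- grain_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                          c(1, 1, 1)),
                    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(fill_holes(bad), "non-manifold")
})

test_that("degenerate slivers are clamped and tallied, not propagated", {
  sliver <- grain_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), rbind(1:3))
  a <- surface_area(sliver)
  expect_equal(as.numeric(a), 0)
  expect_gte(attr(a, "slivers"), 0)
})

test_that("mesh container enforces its invariants", {
  expect_error(grain_mesh(matrix(0, 2, 3), rbind(c(1, 2, 3))), "range")
  expect_error(grain_mesh(matrix(0, 3, 3), rbind(c(1, 2, 2))), "degenerate")
})
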