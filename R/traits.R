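#' Oriented bounding box of a grain
#'
#' Re-expresses the grain cloud in its principal-axis frame (see
#' [pca_transform()]) and measures the axis-aligned extents there:
#' `l = x_max - x_min`, `w = y_max - y_min`, `h = z_max - z_min`. With the
#' axes sorted by descending variance the extents come out ordered
#' `l >= w >= h` up to sampling noise; the reported extents are reordered
#' descending so the invariant holds exactly.
#'
#' @param cloud a [point_cloud] with at least 4 points and full-rank
#'   covariance.
#' @return A list with `box` (class `oriented_box`: `frame`, a
#'   `rigid_transform`, and `extents = c(l, w, h)`) and `cloud`, the input
#'   re-expressed in the OBB frame (`frame = "obb"`).
#' @export
oriented_bbox <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 4) {
    stop("oriented_bbox needs at least 4 points", call. = FALSE)
  }
  pc <- pca_transform(cloud)
  q <- pc$cloud$points
  cv <- crossprod(sweep(cloud$points, 2, colMeans(cloud$points))) / nrow(q)
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-12 * sum(diag(cv))) {
    stop("degenerate geometry: rank-deficient covariance", call. = FALSE)
  }
  ext <- apply(q, 2, function(v) diff(range(v)))
  ord <- order(-ext)
  if (!identical(ord, 1:3)) {
    # variance order and extent order can disagree on near-isotropic
    # clouds; permute the frame so extents are descending
    perm <- diag(3)[ord, , drop = FALSE]
    if (det(perm) < 0) perm[3, ] <- -perm[3, ]
    rot <- perm %*% pc$transform$rotation
    q <- q %*% t(perm)
    ext <- ext[ord]
    pc$transform <- rigid_transform(rot, pc$transform$translation)
  }
  obb_cloud <- point_cloud(q, frame = "obb")
  if (!is.null(cloud$normals)) {
    obb_cloud <- point_cloud(q, cloud$normals %*% t(pc$transform$rotation),
                             cloud$curvature, frame = "obb")
  }
  box <- structure(list(frame = pc$transform,
                        extents = stats::setNames(ext, c("l", "w", "h"))),
                   class = "oriented_box")
  list(box = box, cloud = obb_cloud)
}

#' Planar projection of a grain cloud
#'
#' Projects an OBB-frame cloud onto one of the three principal planes
#' (cross section `yz` at x = 0, longitudinal section `xz` at y = 0,
#' horizontal section `xy` at z = 0), then recovers the projected outline
#' as a concave hull: the 2D Delaunay triangulation keeps every triangle
#' whose longest edge is at most `alpha_mult` times the scan point
#' spacing (estimated from the 3D 6th-nearest-neighbour distance). Area
#' is the summed area of the kept triangles; the perimeter is the length
#' of the traced outer outline loop, so interior pinholes left by the
#' filter do not contribute.
#'
#' @param cloud_obb a [point_cloud] in the OBB frame.
#' @param section `"cross"`, `"longitudinal"` or `"horizontal"`.
#' @param alpha_mult longest-edge multiplier of the concave-hull filter
#'   (default 3).
#' @return An object of class `projection_2d` with fields `section`,
#'   `points` (M x 2), `area_mm2`, `perimeter_mm`, `boundary` (B x 2 index
#'   matrix of boundary edges into `points`).
#' @export
project_section <- function(cloud_obb,
                            section = c("cross", "longitudinal", "horizontal"),
                            alpha_mult = 3) {
  stopifnot(inherits(cloud_obb, "point_cloud"))
  section <- match.arg(section)
  drop_axis <- switch(section, cross = 1L, longitudinal = 2L, horizontal = 3L)
  pts2 <- cloud_obb$points[, -drop_axis, drop = FALSE]
  if (nrow(pts2) < 3) stop("degenerate projection: fewer than 3 points", call. = FALSE)
  # The length scale of the alpha filter is the 3D scan point spacing
  # (the projection superimposes the front and back surface sheets, so a
  # 2D nearest-neighbour distance would collapse). The spacing is
  # estimated from the 6th-nearest-neighbour distance, whose median is
  # about 1.35 point spacings for Poisson-like samplings and about 1.4
  # pitches on a square grid, making the estimate insensitive to the
  # nearest-neighbour statistics of the sampling process.
  k6 <- min(6L, nrow(cloud_obb$points) - 1L)
  sp <- FNN::get.knn(cloud_obb$points, k = k6)$nn.dist[, k6]
  med_sp <- stats::median(sp[sp > 0]) / 1.35
  if (!is.finite(med_sp) || med_sp <= 0) {
    stop("degenerate projection: all points coincide", call. = FALSE)
  }
  jit <- with_local_seed(99992L, matrix(stats::runif(length(pts2), -1, 1),
                                        nrow(pts2), 2)) * 1e-6 * med_sp
  pj <- pts2 + jit
  tm <- tryCatch(suppressWarnings(interp::tri.mesh(pj[, 1], pj[, 2])),
                 error = function(e) stop("projection triangulation failed",
                                          call. = FALSE))
  tr <- interp::triangles(tm)[, 1:3, drop = FALSE]
  edge_len <- function(i, j) sqrt(rowSums((pts2[i, , drop = FALSE] -
                                             pts2[j, , drop = FALSE])^2))
  lmax <- pmax(edge_len(tr[, 1], tr[, 2]),
               edge_len(tr[, 2], tr[, 3]),
               edge_len(tr[, 3], tr[, 1]))
  keep <- tr[lmax <= alpha_mult * med_sp, , drop = FALSE]
  if (nrow(keep) == 0) stop("concave hull empty: alpha_mult too small", call. = FALSE)
  x <- pts2[, 1]; y <- pts2[, 2]
  cross_z <- (x[keep[, 2]] - x[keep[, 1]]) * (y[keep[, 3]] - y[keep[, 1]]) -
    (x[keep[, 3]] - x[keep[, 1]]) * (y[keep[, 2]] - y[keep[, 1]])
  area <- sum(0.5 * abs(cross_z))
  # orient kept triangles counter-clockwise, take the directed edges that
  # belong to exactly one triangle, and trace them into loops; the
  # perimeter is the length of the outline (the loop of largest enclosed
  # area), so interior pinholes left by the alpha filter do not count
  cw <- cross_z < 0
  keep[cw, 2:3] <- keep[cw, 3:2]
  da <- c(keep[, 1], keep[, 2], keep[, 3])
  db <- c(keep[, 2], keep[, 3], keep[, 1])
  n2 <- nrow(pts2)
  ukey <- (pmin(da, db) - 1) * as.numeric(n2) + pmax(da, db) - 1
  tb <- table(ukey)
  open_keys <- as.numeric(names(tb)[tb == 1])
  sel <- ukey %in% open_keys
  from <- da[sel]
  to <- db[sel]
  loops <- trace_cycles(from, to)
  if (length(loops) == 0) {
    # fallback: raw boundary edge sum
    perimeter <- sum(edge_len(from, to))
    outline <- cbind(from, to)
  } else {
    loop_area <- vapply(loops, function(lp) {
      xs <- x[lp]; ys <- y[lp]
      abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    }, numeric(1))
    outline_loop <- loops[[which.max(loop_area)]]
    nxt <- c(outline_loop[-1], outline_loop[1])
    perimeter <- sum(edge_len(outline_loop, nxt))
    outline <- cbind(outline_loop, nxt)
  }
  structure(list(section = section, points = pts2, area_mm2 = area,
                 perimeter_mm = perimeter, boundary = outline),
            class = "projection_2d")
}

#' Compactness index of a closed outline
#'
#' `C^2 / (4 pi A)` for a closed planar curve of perimeter `C` and area
#' `A`: 1 for a circle and greater than 1 for any other simple closed
#' curve (isoperimetric inequality), so larger values mean less circular
#' sections.
#'
#' @param perimeter_mm outline perimeter (> 0).
#' @param area_mm2 enclosed area (> 0).
#' @return The dimensionless compactness index.
#' @export
#' @examples
#' compactness(2 * pi, pi)  # circle of radius 1 -> exactly 1
#' compactness(4, 1)        # unit square -> 4 / pi
compactness <- function(perimeter_mm, area_mm2) {
  if (!is.numeric(perimeter_mm) || !is.numeric(area_mm2) ||
      any(perimeter_mm <= 0) || any(area_mm2 <= 0)) {
    stop("perimeter and area must be positive", call. = FALSE)
  }
  perimeter_mm^2 / (4 * pi * area_mm2)
}

#' Compute the 25 phenotypic traits of one grain
#'
#' Full single-grain pipeline: oriented bounding box (length, width,
#' thickness), greedy projection triangulation and hole filling in the OBB
#' frame, Heron-sum surface area, prism-projection volume, the three
#' principal-plane projections (perimeters, areas), and the derived
#' ratios and compactness indices. Derived traits are computed exactly
#' from the basic ones, so the algebraic identities among the table
#' columns hold to machine precision.
#'
#' @param segment a `grain_segment` (or a bare [point_cloud], which gets
#'   `grain_id = NA`).
#' @param config a [grain_config()]; the meshing and projection parameters
#'   are taken from it.
#' @return An object of class `grain_traits`: `grain_id`, `traits` (named
#'   numeric vector in [trait_names()] order), `box` (the `oriented_box`),
#'   `mesh` (the closed [grain_mesh] in the OBB frame).
#' @export
compute_traits <- function(segment, config = grain_config()) {
  if (inherits(segment, "point_cloud")) {
    segment <- structure(list(grain_id = NA_integer_, cloud = segment,
                              centroid = colMeans(segment$points),
                              grid_cell = NULL), class = "grain_segment")
  }
  stopifnot(inherits(segment, "grain_segment"))
  id_tag <- if (is.na(segment$grain_id)) "grain" else
    sprintf("grain %d", segment$grain_id)
  res <- tryCatch({
    ob <- oriented_bbox(segment$cloud)
    cl <- ob$cloud
    if (is.null(cl$normals)) cl <- estimate_normals(cl, min(config$normal_k,
                                                            n_points(cl) - 1))
    # the search radius is derived from the observed point spacing rather
    # than taken from the config, so traits stay covariant under spatial
    # rescaling of the input cloud
    mesh <- triangulate_surface(cl, radius_mm = NULL,
                                mu = config$mesh_mu,
                                max_angle_deg = config$mesh_max_angle_deg)
    mesh <- close_mesh(mesh)
    s_area <- as.numeric(surface_area(mesh))
    vol <- volume_prism(mesh)
    pr <- lapply(c("cross", "longitudinal", "horizontal"), function(sec) {
      project_section(cl, sec, config$projection_alpha_mult)
    })
    ext <- ob$box$extents
    l <- ext[["l"]]; w <- ext[["w"]]; h <- ext[["h"]]
    tv <- c(
      l = l, w = w, h = h, V = vol, S = s_area,
      C_yz = pr[[1]]$perimeter_mm, S_yz = pr[[1]]$area_mm2,
      C_xz = pr[[2]]$perimeter_mm, S_xz = pr[[2]]$area_mm2,
      C_xy = pr[[3]]$perimeter_mm, S_xy = pr[[3]]$area_mm2,
      l_w = l / w, l_h = l / h, w_h = w / h,
      V_obb = l * w * h,
      S_V = s_area / vol, S_l = s_area / l, S_w = s_area / w, S_h = s_area / h,
      V_l = vol / l, V_w = vol / w, V_h = vol / h,
      c_yz = compactness(pr[[1]]$perimeter_mm, pr[[1]]$area_mm2),
      c_xz = compactness(pr[[2]]$perimeter_mm, pr[[2]]$area_mm2),
      c_xy = compactness(pr[[3]]$perimeter_mm, pr[[3]]$area_mm2)
    )
    structure(list(grain_id = segment$grain_id, traits = tv[trait_names()],
                   box = ob$box, mesh = mesh), class = "grain_traits")
  }, error = function(e) {
    stop(sprintf("%s: %s", id_tag, conditionMessage(e)), call. = FALSE)
  })
  res
}

#' @export
print.grain_traits <- function(x, ...) {
  cat(sprintf("<grain_traits> grain_id = %s\n",
              ifelse(is.na(x$grain_id), "NA", x$grain_id)))
  print(round(x$traits, 4))
  invisible(x)
}
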