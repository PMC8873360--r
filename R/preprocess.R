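#' Principal-axis coordinate transform
#'
#' Moves the cloud to its centroid and rotates it onto the eigenvectors of
#' the coordinate covariance matrix, sorted by descending eigenvalue, so
#' the first output axis carries the largest variance. This is the
#' transform that turns the axis-aligned bounding box of a grain into its
#' oriented bounding box.
#'
#' Determinism conventions (the eigendecomposition alone fixes neither the
#' eigenvector signs nor tied orders): each eigenvector's
#' largest-magnitude component is made positive; near-equal eigenvalues
#' are ordered by lexicographic comparison of the sign-fixed vectors; and
#' the third axis is flipped if needed so the rotation is proper
#' (determinant +1).
#'
#' @param cloud a [point_cloud] with at least 3 points.
#' @return A list with `cloud` (the transformed [point_cloud], centroid at
#'   the origin, covariance diagonal) and `transform` (a `rigid_transform`
#'   with fields `rotation`, a 3 x 3 matrix whose rows are the unit
#'   eigenvectors, and `translation`, the original centroid).
#' @export
#' @examples
#' pc <- point_cloud(cbind(runif(100, 0, 8), runif(100, 0, 3), runif(100, 0, 2)))
#' tr <- pca_transform(pc)
#' colMeans(tr$cloud$points)  # ~ (0, 0, 0)
pca_transform <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  if (nrow(p) < 3) {
    stop("degenerate geometry: pca_transform needs at least 3 points", call. = FALSE)
  }
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  cv <- crossprod(q) / nrow(q)
  if (!all(is.finite(cv)) || sum(diag(cv)) <= 0) {
    stop("degenerate geometry: zero covariance (all points coincide)", call. = FALSE)
  }
  rot <- principal_axes(cv)
  tf <- rigid_transform(rot, ctr)
  list(cloud = point_cloud(q %*% t(rot), frame = "pca"), transform = tf)
}

# Rows of the returned matrix are unit eigenvectors of `cv` by descending
# eigenvalue, sign- and tie-fixed as documented in pca_transform().
principal_axes <- function(cv) {
  eg <- eigen(cv, symmetric = TRUE)
  vec <- eg$vectors  # columns, descending eigenvalues
  # sign fix: largest-magnitude component positive
  for (j in 1:3) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  # lexicographic order within (near-)tied eigenvalues
  lam <- eg$values
  tol <- 1e-12 * max(sum(abs(lam)), 1)
  ord <- order(-lam)
  grp <- cumsum(c(TRUE, diff(lam[ord]) < -tol))
  for (g in unique(grp)) {
    idx <- ord[grp == g]
    if (length(idx) > 1) {
      key <- apply(round(vec[, idx, drop = FALSE], 12), 2, paste, collapse = ",")
      ord[grp == g] <- idx[order(key)]
    }
  }
  vec <- vec[, ord, drop = FALSE]
  rot <- t(vec)
  if (det(rot) < 0) rot[3, ] <- -rot[3, ]
  rot
}

rigid_transform <- function(rotation, translation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("rotation must be proper (determinant +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' Computes `rotation %*% (x - translation)` for each row, i.e. maps
#' coordinates from the frame a [pca_transform()] was computed in into the
#' transformed frame.
#'
#' @param transform a `rigid_transform`.
#' @param points N x 3 matrix (or a [point_cloud]).
#' @param inverse if `TRUE`, apply the inverse map.
#' @return Matrix of transformed coordinates (or a [point_cloud] if one was
#'   given; normals are rotated along).
#' @export
apply_transform <- function(transform, points, inverse = FALSE) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(points, "point_cloud")) {
    out <- apply_transform(transform, points$points, inverse)
    nrm <- points$normals
    if (!is.null(nrm)) {
      nrm <- if (inverse) nrm %*% transform$rotation else nrm %*% t(transform$rotation)
    }
    return(point_cloud(out, nrm, points$curvature, frame = points$frame))
  }
  m <- as_coord_matrix(points, "points")
  if (inverse) {
    sweep(m %*% transform$rotation, 2, transform$translation, `+`)
  } else {
    sweep(m, 2, transform$translation) %*% t(transform$rotation)
  }
}

#' Voxel-grid downsampling
#'
#' Overlays a cubic grid of edge `leaf_mm` and replaces all points of each
#' occupied voxel by their gravity centre (arithmetic mean). Voxel indices
#' are `floor(coordinate / leaf_mm)` in the cloud's own frame, with no
#' origin snapping. Normals and curvature are dropped: they refer to the
#' original points and should be re-estimated on the reduced cloud.
#'
#' @param cloud a [point_cloud].
#' @param leaf_mm voxel edge length in mm (> 0).
#' @return A [point_cloud] with one point per occupied voxel, ordered by
#'   first occurrence of the voxel in the input.
#' @export
voxel_downsample <- function(cloud, leaf_mm) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.numeric(leaf_mm) || length(leaf_mm) != 1 || !is.finite(leaf_mm) ||
      leaf_mm <= 0) {
    stop("`leaf_mm` must be a single positive number", call. = FALSE)
  }
  p <- cloud$points
  if (nrow(p) == 0) return(with_points(cloud, p))
  ix <- floor(p[, 1] / leaf_mm)
  iy <- floor(p[, 2] / leaf_mm)
  iz <- floor(p[, 3] / leaf_mm)
  dt <- data.table::data.table(ix = ix, iy = iy, iz = iz,
                               x = p[, 1], y = p[, 2], z = p[, 3])
  agg <- dt[, list(x = mean(x), y = mean(y), z = mean(z)),
            by = c("ix", "iy", "iz")]
  with_points(cloud, as.matrix(agg[, c("x", "y", "z")]))
}

#' Statistical outlier filter
#'
#' For each point, the mean distance to its `k` nearest neighbours is
#' computed; points whose mean distance exceeds the global mean plus
#' `std_mult` standard deviations of those per-point means are removed.
#' Points are never moved, only dropped, so the output is always a subset
#' of the input.
#'
#' @param cloud a [point_cloud] with more than `k` points.
#' @param k neighbourhood size (>= 1).
#' @param std_mult threshold multiplier (> 0).
#' @return The filtered [point_cloud] (normals/curvature subset along).
#' @export
statistical_outlier_filter <- function(cloud, k = 50, std_mult = 1.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  n <- n_points(cloud)
  if (n <= k) {
    stop(sprintf("cloud has %d points, need more than k = %d", n, k), call. = FALSE)
  }
  if (!is.finite(std_mult) || std_mult <= 0) {
    stop("`std_mult` must be positive", call. = FALSE)
  }
  nnd <- FNN::get.knn(cloud$points, k = k)$nn.dist
  md <- rowMeans(nnd)
  keep <- md <= mean(md) + std_mult * stats::sd(md)
  subset_cloud(cloud, which(keep))
}

#' Standard preprocessing chain
#'
#' Principal-axis transform, voxel downsampling, statistical outlier
#' filtering, in that order.
#'
#' @param cloud a [point_cloud].
#' @param config a [grain_config()].
#' @return A list with `cloud` (the preprocessed [point_cloud]) and
#'   `transform` (the `rigid_transform` of the principal-axis step).
#' @export
preprocess_cloud <- function(cloud, config = grain_config()) {
  pc <- pca_transform(cloud)
  out <- voxel_downsample(pc$cloud, config$voxel_leaf_mm)
  if (n_points(out) > config$outlier_k) {
    out <- statistical_outlier_filter(out, config$outlier_k, config$outlier_std_mult)
  }
  list(cloud = out, transform = pc$transform)
}
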