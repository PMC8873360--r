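#' Estimate per-point normals and curvature
#'
#' Classical PCA normals: for each point the covariance of its `k` nearest
#' neighbours (self included) is decomposed; the eigenvector of the
#' smallest eigenvalue is the normal and the surface-variation ratio
#' `lambda_0 / (lambda_0 + lambda_1 + lambda_2)` (in `[0, 1/3]`) is stored
#' as curvature. Normals are re-oriented to point away from the cloud
#' centroid, which is globally consistent for the closed, star-shaped
#' surfaces this pipeline meets.
#'
#' @param cloud a [point_cloud] with more than `k` points.
#' @param k neighbourhood size (>= 3).
#' @return The same cloud with `normals` and `curvature` filled in.
#' @export
estimate_normals <- function(cloud, k = 30) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (k < 3) stop("`k` must be at least 3", call. = FALSE)
  n <- n_points(cloud)
  if (n <= k) stop(sprintf("cloud has %d points, need more than k = %d", n, k),
                   call. = FALSE)
  p <- cloud$points
  idx <- cbind(seq_len(n), FNN::get.knn(p, k = k)$nn.index)
  m <- ncol(idx)
  # neighbourhood coordinate sums, vectorized across all points
  gx <- matrix(p[idx, 1], n, m)
  gy <- matrix(p[idx, 2], n, m)
  gz <- matrix(p[idx, 3], n, m)
  mx <- rowMeans(gx); my <- rowMeans(gy); mz <- rowMeans(gz)
  cxx <- rowMeans(gx * gx) - mx * mx
  cyy <- rowMeans(gy * gy) - my * my
  czz <- rowMeans(gz * gz) - mz * mz
  cxy <- rowMeans(gx * gy) - mx * my
  cxz <- rowMeans(gx * gz) - mx * mz
  cyz <- rowMeans(gy * gz) - my * mz
  normals <- matrix(0, n, 3)
  curv <- numeric(n)
  for (i in seq_len(n)) {
    cv <- matrix(c(cxx[i], cxy[i], cxz[i],
                   cxy[i], cyy[i], cyz[i],
                   cxz[i], cyz[i], czz[i]), 3, 3)
    eg <- eigen(cv, symmetric = TRUE)
    normals[i, ] <- eg$vectors[, 3]
    tot <- sum(eg$values)
    curv[i] <- if (tot > 0) max(0, eg$values[3]) / tot else 0
  }
  ctr <- colMeans(p)
  outward <- rowSums(normals * sweep(p, 2, ctr)) < 0
  normals[outward, ] <- -normals[outward, ]
  nn <- sqrt(rowSums(normals^2))
  normals <- normals / nn
  point_cloud(p, normals, pmin(curv, 1 / 3), frame = cloud$frame)
}

#' Fit the stage plane with RANSAC
#'
#' Best-of-`iters` three-point hypotheses scored by inlier count at
#' absolute point-plane distance `dist_mm`, with ties resolved in favour of
#' the earliest iteration, followed by a total-least-squares refit
#' (smallest covariance eigenvector) on the winning inlier set.
#' Deterministic for a fixed seed.
#'
#' @param cloud a [point_cloud] with at least 3 points.
#' @param dist_mm inlier distance threshold in mm.
#' @param iters number of hypotheses.
#' @param seed integer seed.
#' @return A `plane_model`: `normal` (unit vector, largest-magnitude
#'   component positive), `offset_mm` (plane is `normal . x = offset_mm`),
#'   `inlier_indices` (w.r.t. the refit plane), `dist_mm`.
#' @export
fit_plane_ransac <- function(cloud, dist_mm = 0.2, iters = 200, seed = 1) {
  stopifnot(inherits(cloud, "point_cloud"), dist_mm > 0, iters >= 1)
  p <- cloud$points
  n <- nrow(p)
  if (n < 3) stop("RANSAC plane fit needs at least 3 points", call. = FALSE)
  with_local_seed(seed, {
    best_count <- -1L
    best_nrm <- NULL
    best_off <- NULL
    for (it in seq_len(iters)) {
      tri <- sample.int(n, 3)
      a <- p[tri[1], ]; b <- p[tri[2], ]; c3 <- p[tri[3], ]
      nrm <- cross3(b - a, c3 - a)
      ln <- sqrt(sum(nrm^2))
      if (ln < 1e-12) next  # collinear sample
      nrm <- nrm / ln
      off <- sum(nrm * a)
      cnt <- sum(abs(p %*% nrm - off) <= dist_mm)
      if (cnt > best_count) {
        best_count <- cnt
        best_nrm <- nrm
        best_off <- off
      }
    }
    if (is.null(best_nrm) || best_count < 3) {
      stop("RANSAC failed: no plane hypothesis with at least 3 inliers", call. = FALSE)
    }
    # total-least-squares refit on the inliers of the winning hypothesis
    inl <- which(abs(p %*% best_nrm - best_off) <= dist_mm)
    ctr <- colMeans(p[inl, , drop = FALSE])
    cv <- crossprod(sweep(p[inl, , drop = FALSE], 2, ctr)) / length(inl)
    nrm <- eigen(cv, symmetric = TRUE)$vectors[, 3]
    k <- which.max(abs(nrm))
    if (nrm[k] < 0) nrm <- -nrm
    off <- sum(nrm * ctr)
    inl <- which(abs(p %*% nrm - off) <= dist_mm)
    structure(list(normal = nrm, offset_mm = off, inlier_indices = inl,
                   dist_mm = dist_mm), class = "plane_model")
  })
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Remove the stage plane from a scene
#'
#' Keeps points whose signed distance from the plane exceeds `margin_mm`
#' on the grain side. The grain side is the half-space holding the
#' majority of the points that are clearly off the plane (beyond the fit
#' threshold).
#'
#' @param cloud a [point_cloud].
#' @param plane a `plane_model` from [fit_plane_ransac()].
#' @param margin_mm clearance in mm (default 0.5).
#' @return The [point_cloud] of above-plane points (a warning is emitted,
#'   not an error, when nothing survives).
#' @export
remove_plane <- function(cloud, plane, margin_mm = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(plane, "plane_model"))
  s <- as.numeric(cloud$points %*% plane$normal - plane$offset_mm)
  off_plane <- abs(s) > plane$dist_mm
  side <- if (sum(s[off_plane] > 0) >= sum(s[off_plane] < 0)) 1 else -1
  keep <- which(side * s > margin_mm)
  if (length(keep) == 0) {
    warning("no points remain above the stage plane", call. = FALSE)
  }
  subset_cloud(cloud, keep)
}

#' Region growing segmentation
#'
#' Splits a cloud into smooth clusters. Seeds are processed in ascending
#' curvature order; a neighbour joins the current region when the
#' (undirected) angle between its normal and the current point's normal is
#' at most `angle_deg`, and additionally becomes a growth front itself
#' when its curvature is at most `curvature_max`. Clusters outside
#' `[min_pts, max_pts]` are discarded. Cluster ids are assigned row-major
#' by stage position (descending y rows, then ascending x), matching the
#' manual bookkeeping of the batch layout.
#'
#' @param cloud a [point_cloud] with normals and curvature
#'   (see [estimate_normals()]).
#' @param angle_deg normal-angle threshold in degrees.
#' @param curvature_max seed curvature threshold.
#' @param min_pts,max_pts accepted cluster size range.
#' @param k neighbourhood size (default 30).
#' @param row_tol_mm gap in y beyond which centroids are considered to be
#'   on different rows when ordering clusters (default 10).
#' @return A list of `grain_segment` objects (`grain_id`, `cloud`,
#'   `centroid`, `grid_cell`); empty, with a warning, when no cluster
#'   survives.
#' @export
region_growing <- function(cloud, angle_deg = 30, curvature_max = 0.20,
                           min_pts = 200, max_pts = 200000, k = 30,
                           row_tol_mm = 10) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$normals) || is.null(cloud$curvature)) {
    stop("region_growing needs normals and curvature; run estimate_normals first",
         call. = FALSE)
  }
  if (min_pts < 1) stop("`min_pts` must be at least 1", call. = FALSE)
  n <- n_points(cloud)
  if (n == 0) {
    warning("empty cloud: no clusters", call. = FALSE)
    return(list())
  }
  p <- cloud$points
  nrm <- cloud$normals
  curv <- cloud$curvature
  k <- min(k, n - 1)
  nn_idx <- FNN::get.knn(p, k = k)$nn.index
  cos_thr <- cos(angle_deg * pi / 180)
  label <- integer(n)
  queue <- integer(n)
  n_clusters <- 0L
  seed_order <- order(curv)
  for (s in seed_order) {
    if (label[s] != 0L) next
    n_clusters <- n_clusters + 1L
    label[s] <- n_clusters
    queue[1] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      nb <- nn_idx[cur, ]
      nb <- nb[label[nb] == 0L]
      if (length(nb) == 0) next
      dots <- abs(nrm[nb, , drop = FALSE] %*% nrm[cur, ])
      joins <- nb[dots >= cos_thr]
      if (length(joins) == 0) next
      label[joins] <- n_clusters
      front <- joins[curv[joins] <= curvature_max]
      if (length(front) > 0) {
        queue[(tail + 1L):(tail + length(front))] <- front
        tail <- tail + length(front)
      }
    }
  }
  sizes <- tabulate(label, nbins = n_clusters)
  keep_ids <- which(sizes >= min_pts & sizes <= max_pts)
  if (length(keep_ids) == 0) {
    warning("no clusters within the accepted size range", call. = FALSE)
    return(list())
  }
  segs <- lapply(keep_ids, function(cl) {
    idx <- which(label == cl)
    sc <- subset_cloud(cloud, idx)
    list(cloud = sc, centroid = colMeans(sc$points))
  })
  # row-major ordering on stage coordinates: rows found by y-gaps
  cx <- vapply(segs, function(s) s$centroid[1], numeric(1))
  cy <- vapply(segs, function(s) s$centroid[2], numeric(1))
  ord_y <- order(-cy)
  row_id <- cumsum(c(1, diff(-cy[ord_y]) > row_tol_mm))
  ord <- ord_y[order(row_id, cx[ord_y])]
  segs <- segs[ord]
  mapply(function(s, id) {
    structure(list(grain_id = id, cloud = s$cloud, centroid = s$centroid,
                   grid_cell = NULL), class = "grain_segment")
  }, segs, seq_along(segs), SIMPLIFY = FALSE)
}

#' Match segments to layout cells
#'
#' Assigns each segment the nearest cell of the stage grid (centres taken
#' in the same frame as the segment centroids). The assignment must be
#' injective; two segments claiming the same cell raise an error naming
#' both.
#'
#' @param segments list of `grain_segment` objects.
#' @param layout a [grid_layout()].
#' @param centers optional N x 2 matrix overriding `layout$centers`
#'   (e.g. layout centres mapped through the scene's PCA transform).
#' @return The segments with `grid_cell` set to `c(row, col)` (extra cells
#'   get row 0).
#' @export
assign_grid_cells <- function(segments, layout = grid_layout(), centers = NULL) {
  if (length(segments) == 0) return(segments)
  ctr <- if (is.null(centers)) layout$centers else as.matrix(centers)
  if (length(segments) > nrow(ctr)) {
    stop(sprintf("%d segments cannot be assigned injectively to %d cells",
                 length(segments), nrow(ctr)), call. = FALSE)
  }
  pos <- do.call(rbind, lapply(segments, function(s) s$centroid[1:2]))
  nearest <- FNN::get.knnx(ctr, pos, k = 1)$nn.index[, 1]
  dup <- which(duplicated(nearest) | duplicated(nearest, fromLast = TRUE))
  if (length(dup) > 0) {
    cell <- nearest[dup[1]]
    claimants <- which(nearest == cell)
    stop(sprintf("grid cell collision: segments %s are all nearest to cell %d",
                 paste(vapply(segments[claimants], `[[`, integer(1), "grain_id"),
                       collapse = ", "), cell), call. = FALSE)
  }
  for (i in seq_along(segments)) {
    segments[[i]]$grid_cell <- c(layout$cell$row[nearest[i]],
                                 layout$cell$col[nearest[i]])
  }
  segments
}

#' Segment a preprocessed scene into single-grain clouds
#'
#' RANSAC stage-plane fit, plane removal, normal/curvature estimation and
#' region growing, using the thresholds in `config`.
#'
#' @param cloud the preprocessed scene [point_cloud].
#' @param config a [grain_config()].
#' @return A list with `segments` (list of `grain_segment`), `plane` (the
#'   `plane_model`) and `above_plane` (the plane-free [point_cloud]).
#' @export
segment_scene <- function(cloud, config = grain_config()) {
  plane <- fit_plane_ransac(cloud, config$plane_dist_mm, config$ransac_iters,
                            config$ransac_seed)
  above <- remove_plane(cloud, plane, config$plane_margin_mm)
  segs <- list()
  if (n_points(above) > config$normal_k) {
    above <- estimate_normals(above, config$normal_k)
    segs <- region_growing(above, config$rg_normal_angle_deg,
                           config$rg_curvature_max, config$rg_min_points,
                           config$rg_max_points, k = config$rg_k)
  }
  list(segments = segs, plane = plane, above_plane = above)
}
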