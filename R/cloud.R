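#' Point cloud container
#'
#' A `point_cloud` is the basic data carrier of the package: an N x 3 matrix
#' of coordinates in millimetres, optionally with unit surface normals and a
#' per-point curvature estimate, plus a tag recording which frame the
#' coordinates live in (`"scanner"` for raw input, `"pca"` after the global
#' principal-axis transform, `"obb"` for a single grain expressed in its
#' oriented-bounding-box frame).
#'
#' @param points numeric matrix (or coercible) with 3 columns, coordinates in mm.
#' @param normals optional N x 3 matrix of unit outward normals.
#' @param curvature optional numeric vector of length N (dimensionless,
#'   surface-variation estimate in `[0, 1/3]`); only allowed when `normals`
#'   are present.
#' @param frame one of `"scanner"`, `"pca"`, `"obb"`.
#' @return An object of class `point_cloud`.
#' @export
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' n_points(pc)
point_cloud <- function(points, normals = NULL, curvature = NULL,
                        frame = c("scanner", "pca", "obb")) {
  frame <- match.arg(frame)
  points <- as_coord_matrix(points, "points")
  if (!is.null(normals)) {
    normals <- as_coord_matrix(normals, "normals")
    if (nrow(normals) != nrow(points)) {
      stop("`normals` must have one row per point", call. = FALSE)
    }
    nrm <- sqrt(rowSums(normals^2))
    if (nrow(normals) > 0 && any(abs(nrm - 1) > 1e-6)) {
      stop("`normals` rows must be unit vectors (tolerance 1e-6)", call. = FALSE)
    }
  }
  if (!is.null(curvature)) {
    if (is.null(normals)) {
      stop("`curvature` may only be present when `normals` are present",
           call. = FALSE)
    }
    curvature <- as.numeric(curvature)
    if (length(curvature) != nrow(points)) {
      stop("`curvature` must have one value per point", call. = FALSE)
    }
  }
  structure(
    list(points = points, normals = normals, curvature = curvature,
         frame = frame),
    class = "point_cloud"
  )
}

as_coord_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x) || length(x) == 0) {
    x <- matrix(numeric(0), ncol = 3)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3) stop(sprintf("`%s` must have 3 columns", what), call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (nrow(x) > 0 && !all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite coordinates", what), call. = FALSE)
  }
  x
}

#' Number of points in a cloud
#' @param cloud a [point_cloud].
#' @return integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points [frame: %s]%s%s\n",
              nrow(x$points), x$frame,
              if (!is.null(x$normals)) ", with normals" else "",
              if (!is.null(x$curvature)) ", with curvature" else ""))
  if (nrow(x$points) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

# Replace coordinates, dropping normals/curvature (which a coordinate change
# generally invalidates) unless `keep_attrs` is TRUE.
with_points <- function(cloud, points, frame = cloud$frame, keep_attrs = FALSE) {
  if (keep_attrs) {
    point_cloud(points, cloud$normals, cloud$curvature, frame)
  } else {
    point_cloud(points, frame = frame)
  }
}

# Subset a cloud by point index, carrying normals/curvature along.
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE],
              if (!is.null(cloud$curvature)) cloud$curvature[idx],
              frame = cloud$frame)
}
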