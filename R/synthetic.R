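#' Grain specification for the synthetic generator
#'
#' Ground-truth description of one synthetic grain: a superellipsoid with
#' semi-axes `length_mm/2 >= width_mm/2 >= thickness_mm/2` and shape
#' exponents `(e1, e2)` (both 1 gives an ellipsoid; smaller values give
#' blockier outlines, larger values more lens-like ones), standing
#' vertically (long axis up) at a 2D stage position with a yaw about the
#' vertical axis.
#'
#' @param length_mm,width_mm,thickness_mm grain dimensions in mm,
#'   `length_mm >= width_mm >= thickness_mm > 0`.
#' @param shape_exponents numeric pair `(e1, e2)` of positive superellipsoid
#'   exponents; `e1` shapes the profile along the long axis, `e2` the
#'   cross-section.
#' @param position_mm stage coordinates (x, y) of the grain centre in mm.
#' @param yaw_deg rotation about the vertical axis in degrees.
#' @param label `"filled"` or `"unfilled"`.
#' @param variety free-form variety tag.
#' @return An object of class `grain_spec`.
#' @export
grain_spec <- function(length_mm, width_mm, thickness_mm,
                       shape_exponents = c(1, 1), position_mm = c(0, 0),
                       yaw_deg = 0, label = c("filled", "unfilled"),
                       variety = "synthetic") {
  label <- match.arg(label)
  stopifnot(is.numeric(shape_exponents), length(shape_exponents) == 2,
            all(shape_exponents > 0), length(position_mm) == 2)
  if (!(length_mm >= width_mm && width_mm >= thickness_mm && thickness_mm > 0)) {
    stop("grain dimensions must satisfy length >= width >= thickness > 0",
         call. = FALSE)
  }
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 thickness_mm = thickness_mm,
                 shape_exponents = as.numeric(shape_exponents),
                 position_mm = as.numeric(position_mm),
                 yaw_deg = yaw_deg, label = label, variety = variety),
            class = "grain_spec")
}

#' Stage grid layout
#'
#' Cell centres of the batch placement grid: `rows x cols` cells spaced
#' `spacing_mm` apart, centred on the stage origin, in row-major order,
#' plus `extra` separately placed cells below the grid (the default
#' `6 x 4 + 1` layout holds 25 grains).
#'
#' @param rows,cols grid dimensions.
#' @param extra number of separately placed cells (0 or more).
#' @param spacing_mm centre-to-centre spacing in mm.
#' @return A list with `centers` (N x 2 matrix, row-major order, extra
#'   cells last), `cell` (data frame of row/col indices; extra cells get
#'   row = 0), `rows`, `cols`, `extra`, `spacing_mm`.
#' @export
grid_layout <- function(rows = 4, cols = 6, extra = 1, spacing_mm = 20) {
  stopifnot(rows >= 1, cols >= 1, extra >= 0, spacing_mm > 0)
  xs <- (seq_len(cols) - (cols + 1) / 2) * spacing_mm
  ys <- (seq_len(rows) - (rows + 1) / 2) * spacing_mm
  centers <- cbind(rep(xs, times = rows), rep(rev(ys), each = cols))
  cell <- data.frame(row = rep(seq_len(rows), each = cols),
                     col = rep(seq_len(cols), times = rows))
  if (extra > 0) {
    ex_y <- min(ys) - spacing_mm
    ex_x <- (seq_len(extra) - (extra + 1) / 2) * spacing_mm
    centers <- rbind(centers, cbind(ex_x, rep(ex_y, extra)))
    cell <- rbind(cell, data.frame(row = rep(0L, extra), col = seq_len(extra)))
  }
  dimnames(centers) <- NULL
  list(centers = centers, cell = cell, rows = rows, cols = cols,
       extra = extra, spacing_mm = spacing_mm)
}

#' Scene ground truth
#'
#' @param grains list of [grain_spec] objects.
#' @param plane_z_mm stage plane height in mm.
#' @param layout a [grid_layout()].
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(grains, plane_z_mm = 0, layout = grid_layout()) {
  stopifnot(all(vapply(grains, inherits, logical(1), "grain_spec")))
  if (length(grains) > 0) {
    pos <- do.call(rbind, lapply(grains, `[[`, "position_mm"))
    if (length(grains) > 1) {
      d <- as.matrix(stats::dist(pos))
      diag(d) <- Inf
      if (min(d) < layout$spacing_mm - 1e-9) {
        stop(sprintf("overlapping grains: minimum centre distance %.2f mm < spacing %.2f mm",
                     min(d), layout$spacing_mm), call. = FALSE)
      }
    }
  }
  structure(list(grains = grains, plane_z_mm = plane_z_mm, layout = layout),
            class = "scene_truth")
}

#' Rice-like ground truth for a full stage
#'
#' Builds `n_grains` specs on the grid of `layout`: filled grains draw
#' length/width/thickness around 8 x 3 x 2 mm with mild seeded variation;
#' unfilled grains shrink the thickness by the factor `unfilled_shrink`
#' (the undeveloped endosperm shows up mainly as a thinner grain) and are
#' additionally dented by the generator.
#'
#' @param n_grains number of grains (at most the layout capacity).
#' @param seed integer seed; the builder is a pure function of its
#'   arguments.
#' @param unfilled_frac fraction of unfilled grains (default 0.5).
#' @param unfilled_shrink thickness shrink factor for unfilled grains.
#' @param layout a [grid_layout()].
#' @param plane_z_mm stage height.
#' @return A `scene_truth`.
#' @export
rice_scene_truth <- function(n_grains = 25, seed = 1, unfilled_frac = 0.5,
                             unfilled_shrink = 0.55, layout = grid_layout(),
                             plane_z_mm = 0) {
  stopifnot(n_grains >= 0, n_grains <= nrow(layout$centers))
  with_local_seed(seed, {
    n_unf <- round(n_grains * unfilled_frac)
    labels <- sample(c(rep("unfilled", n_unf), rep("filled", n_grains - n_unf)))
    grains <- lapply(seq_len(n_grains), function(i) {
      l <- stats::rnorm(1, 8.0, 0.35)
      w <- stats::rnorm(1, 3.0, 0.15)
      h <- stats::rnorm(1, 2.0, 0.10)
      if (labels[i] == "unfilled") h <- h * unfilled_shrink
      h <- min(h, w - 1e-6)
      grain_spec(l, w, h,
                 shape_exponents = stats::runif(2, 0.9, 1.3),
                 position_mm = layout$centers[i, ],
                 yaw_deg = stats::runif(1, 0, 360),
                 label = labels[i],
                 variety = "synthetic")
    })
    scene_truth(grains, plane_z_mm = plane_z_mm, layout = layout)
  })
}

# Evaluate an expression with a private RNG stream so generators are pure
# functions of (arguments, seed).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scan of a standard sphere
#'
#' Area-uniform sample of a sphere surface, each point perturbed along its
#' outward normal by zero-mean Gaussian noise. This is the reference
#' object of the surface-area/volume validation protocol.
#'
#' @param radius_mm sphere radius (> 0).
#' @param n_points number of points (>= 4).
#' @param noise_sd_mm Gaussian noise standard deviation along the normal.
#' @param seed integer seed.
#' @return A [point_cloud] with exact outward normals attached.
#' @export
#' @examples
#' pc <- make_sphere_cloud(10, 1000, 0, seed = 1)
#' range(sqrt(rowSums(pc$points^2)))  # exactly 10
make_sphere_cloud <- function(radius_mm, n_points, noise_sd_mm = 0.05, seed = 1) {
  if (!is.numeric(radius_mm) || radius_mm <= 0) {
    stop("`radius_mm` must be positive", call. = FALSE)
  }
  if (n_points < 4) stop("`n_points` must be at least 4", call. = FALSE)
  stopifnot(noise_sd_mm >= 0)
  with_local_seed(seed, {
    z <- stats::runif(n_points, -1, 1)
    th <- stats::runif(n_points, 0, 2 * pi)
    rho <- sqrt(pmax(0, 1 - z^2))
    u <- cbind(rho * cos(th), rho * sin(th), z)
    r <- radius_mm + if (noise_sd_mm > 0) stats::rnorm(n_points, 0, noise_sd_mm) else 0
    point_cloud(u * r, normals = u, frame = "scanner")
  })
}

# superellipsoid implicit function: f(p) = ((|x/a|^(2/e2) + |y/b|^(2/e2))^(e2/e1)
#   + |z/c|^(2/e1)); the surface is f = 1. Star-shaped about the origin for
# all positive exponents, so each direction meets the surface exactly once.
superellipsoid_implicit <- function(p, axes, e) {
  x <- pmax(abs(p[, 1] / axes[1]), 1e-300)
  y <- pmax(abs(p[, 2] / axes[2]), 1e-300)
  z <- pmax(abs(p[, 3] / axes[3]), 1e-300)
  (x^(2 / e[2]) + y^(2 / e[2]))^(e[2] / e[1]) + z^(2 / e[1])
}

# radial distance to the surface along unit directions (rows of u)
superellipsoid_radius <- function(u, axes, e) {
  lo <- rep(0, nrow(u))
  hi <- rep(2 * max(axes), nrow(u))
  for (i in 1:64) {
    mid <- 0.5 * (lo + hi)
    inside <- superellipsoid_implicit(u * mid, axes, e) < 1
    lo <- ifelse(inside, mid, lo)
    hi <- ifelse(inside, hi, mid)
  }
  0.5 * (lo + hi)
}

# outward unit normals by central finite differences of the implicit field
superellipsoid_normal <- function(p, axes, e) {
  h <- 1e-5 * min(axes)
  g <- sapply(1:3, function(j) {
    dp <- matrix(0, nrow(p), 3)
    dp[, j] <- h
    (superellipsoid_implicit(p + dp, axes, e) -
       superellipsoid_implicit(p - dp, axes, e)) / (2 * h)
  })
  g / sqrt(rowSums(g^2))
}

#' Synthetic scan of a single grain
#'
#' Samples the superellipsoid surface of a [grain_spec] approximately
#' uniformly in area (rejection sampling with the area Jacobian of the
#' radial map), perturbs each point along its outward normal, and places
#' the grain vertically: long axis up, rotated by its specified yaw, bottom
#' touching z = 0, centre above its specified stage position.
#'
#' Unfilled grains are additionally dented: the two flat (thickness) faces
#' are displaced inwards by up to `dent_mm`, strongest mid-grain, which
#' emulates the collapsed hull of an undeveloped grain.
#'
#' @param spec a [grain_spec].
#' @param points_per_mm2 target sampling density (default 35 points/mm^2,
#'   about the 0.17 mm structured-light point spacing).
#' @param noise_sd_mm Gaussian surface noise standard deviation
#'   (default 0.05 mm).
#' @param seed integer seed.
#' @param dent_mm dent depth for unfilled grains (default 0.08 mm).
#' @return A [point_cloud] with outward normals; attribute `"area_mm2"`
#'   holds the numerically integrated ground-truth surface area.
#' @export
make_grain_cloud <- function(spec, points_per_mm2 = 35, noise_sd_mm = 0.05,
                             seed = 1, dent_mm = 0.08) {
  stopifnot(inherits(spec, "grain_spec"), points_per_mm2 > 0, noise_sd_mm >= 0)
  axes <- c(spec$length_mm, spec$width_mm, spec$thickness_mm) / 2
  e <- spec$shape_exponents
  with_local_seed(seed, {
    # pilot pool to estimate the area and the weight envelope
    pool_n <- 20000L
    repeat {
      z <- stats::runif(pool_n, -1, 1)
      th <- stats::runif(pool_n, 0, 2 * pi)
      rho <- sqrt(pmax(0, 1 - z^2))
      u <- cbind(rho * cos(th), rho * sin(th), z)
      r <- superellipsoid_radius(u, axes, e)
      p <- u * r
      nrm <- superellipsoid_normal(p, axes, e)
      cosg <- pmax(rowSums(u * nrm), 1e-3)
      w <- r^2 / cosg                      # dA/dOmega
      area <- mean(w) * 4 * pi
      n_target <- max(4L, round(area * points_per_mm2))
      acc <- stats::runif(pool_n) < w / max(w)
      if (sum(acc) >= n_target) break
      pool_n <- as.integer(pool_n * 2)
      if (pool_n > 4e6) stop("superellipsoid sampling failed to converge", call. = FALSE)
    }
    keep <- which(acc)[seq_len(n_target)]
    p <- p[keep, , drop = FALSE]
    nrm <- nrm[keep, , drop = FALSE]

    if (spec$label == "unfilled" && dent_mm > 0) {
      # inward dent on the thickness faces, strongest at mid-length
      depth <- dent_mm * (nrm[, 3]^2) * cos(pi * p[, 1] / spec$length_mm)^2
      p <- p - nrm * depth
    }
    if (noise_sd_mm > 0) {
      p <- p + nrm * stats::rnorm(nrow(p), 0, noise_sd_mm)
    }

    # vertical placement: local length axis (x) -> world z, then yaw, then
    # translate so the exact surface bottom touches z = 0
    r_up <- rbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))  # rot about y by -90 deg
    ya <- spec$yaw_deg * pi / 180
    r_yaw <- rbind(c(cos(ya), -sin(ya), 0), c(sin(ya), cos(ya), 0), c(0, 0, 1))
    rot <- r_yaw %*% r_up
    pw <- p %*% t(rot)
    nw <- nrm %*% t(rot)
    shift <- c(spec$position_mm, axes[1])
    pw <- sweep(pw, 2, shift, `+`)
    out <- point_cloud(pw, normals = nw, frame = "scanner")
    attr(out, "area_mm2") <- area
    out
  })
}

#' Synthetic scan of a full stage scene
#'
#' Union of a noisy planar stage patch (at least 100 x 100 mm, same
#' sampling density as the grains) and one vertically placed grain cloud
#' per [grain_spec] in the truth, with the lowest `occlude_bottom_frac`
#' height fraction of every grain removed to emulate the stage contact
#' shadow.
#'
#' @param truth a [scene_truth].
#' @param points_per_mm2 sampling density (points per mm^2).
#' @param noise_sd_mm Gaussian surface noise sd in mm.
#' @param occlude_bottom_frac fraction of each grain's height removed at
#'   the bottom, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return A [point_cloud] (no normals; estimate them downstream).
#' @export
make_scene <- function(truth, points_per_mm2 = 35, noise_sd_mm = 0.05,
                       occlude_bottom_frac = 0.05, seed = 1) {
  stopifnot(inherits(truth, "scene_truth"))
  if (occlude_bottom_frac < 0 || occlude_bottom_frac >= 0.5) {
    stop("`occlude_bottom_frac` must be in [0, 0.5)", call. = FALSE)
  }
  grains <- truth$grains
  with_local_seed(seed, {
    sub_seeds <- sample.int(2^30, length(grains) + 1)
    half <- max(50, if (nrow(truth$layout$centers) > 0)
      max(abs(truth$layout$centers)) + 15 else 0)
    n_plane <- round((2 * half)^2 * points_per_mm2)
    px <- stats::runif(n_plane, -half, half)
    py <- stats::runif(n_plane, -half, half)
    pz <- truth$plane_z_mm + if (noise_sd_mm > 0)
      stats::rnorm(n_plane, 0, noise_sd_mm) else 0
    parts <- list(cbind(px, py, pz))
    for (i in seq_along(grains)) {
      g <- make_grain_cloud(grains[[i]], points_per_mm2, noise_sd_mm,
                            seed = sub_seeds[i])
      gp <- g$points
      gp[, 3] <- gp[, 3] + truth$plane_z_mm
      if (occlude_bottom_frac > 0) {
        cut <- truth$plane_z_mm + occlude_bottom_frac * grains[[i]]$length_mm
        gp <- gp[gp[, 3] >= cut, , drop = FALSE]
      }
      parts[[i + 1]] <- gp
    }
    point_cloud(do.call(rbind, parts), frame = "scanner")
  })
}
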