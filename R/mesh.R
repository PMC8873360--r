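#' Triangle mesh container
#'
#' Vertices in mm and faces as 1-based vertex index triples. Faces are
#' stored counter-clockwise seen from outside whenever an orientation is
#' known (the mesher orients them by the point normals).
#'
#' @param vertices V x 3 numeric matrix.
#' @param faces F x 3 integer matrix of vertex indices.
#' @return An object of class `grain_mesh`.
#' @export
grain_mesh <- function(vertices, faces) {
  vertices <- as_coord_matrix(vertices, "vertices")
  if (is.null(faces) || length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  }
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) stop("`faces` must have 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face indices out of vertex range", call. = FALSE)
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen)) {
      stop(sprintf("%d degenerate face(s) with repeated vertices", sum(degen)),
           call. = FALSE)
    }
  }
  structure(list(vertices = vertices, faces = faces), class = "grain_mesh")
}

#' @export
print.grain_mesh <- function(x, ...) {
  be <- nrow(boundary_edges(x))
  cat(sprintf("<grain_mesh> %d vertices, %d faces, %d boundary edges%s\n",
              nrow(x$vertices), nrow(x$faces), be,
              if (be == 0) " (closed)" else ""))
  invisible(x)
}

# undirected edges of all faces, as a data.table with a numeric key
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  v <- nrow(mesh$vertices)
  a <- c(pmin(f[, 1], f[, 2]), pmin(f[, 1], f[, 3]), pmin(f[, 2], f[, 3]))
  b <- c(pmax(f[, 1], f[, 2]), pmax(f[, 1], f[, 3]), pmax(f[, 2], f[, 3]))
  data.table::data.table(ek = (a - 1) * as.numeric(v) + (b - 1),
                         a = a, b = b, face = rep(seq_len(nf), 3))
}

#' Boundary edges of a mesh
#' @param mesh a [grain_mesh].
#' @return Two-column integer matrix of edges incident to exactly one face.
#' @export
boundary_edges <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(matrix(integer(0), ncol = 2))
  et <- mesh_edge_table(mesh)
  cnt <- et[, list(n = .N, a = a[1], b = b[1]), by = "ek"]
  as.matrix(cnt[cnt$n == 1, c("a", "b")])
}

#' Is the mesh closed (watertight)?
#' @param mesh a [grain_mesh].
#' @return `TRUE` when every edge is shared by exactly two faces.
#' @export
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  et <- mesh_edge_table(mesh)
  cnt <- et[, list(n = .N), by = "ek"]$n
  all(cnt == 2)
}

#' Euler characteristic of the referenced mesh
#'
#' `V - E + F` over the vertices actually referenced by faces (the mesher
#' keeps the full point list as the vertex pool, so unreferenced points
#' are excluded here).
#'
#' @param mesh a [grain_mesh].
#' @return Integer Euler characteristic (2 for a topological sphere).
#' @export
euler_characteristic <- function(mesh) {
  v <- length(unique(as.vector(mesh$faces)))
  e <- nrow(unique(mesh_edge_table(mesh)[, "ek"]))
  f <- nrow(mesh$faces)
  v - e + f
}

#' Greedy projection triangulation
#'
#' Advancing-front style surface reconstruction: every point's
#' neighbourhood (nearest neighbours within `radius_mm`, capped at `mu`
#' times the local point spacing, and with normals within `max_angle_deg`
#' of the point's own) is projected onto the point's tangent plane and
#' Delaunay-triangulated in 2D; the triangles of the point's Delaunay star
#' are candidate faces. A face is accepted when at least two of its three
#' vertices generate it (a consistency vote that discards spurious
#' connections), near-degenerate slivers are removed, edges claimed by
#' more than two faces are repaired by dropping the lowest-vote claimants,
#' and faces are oriented by the point normals.
#'
#' A deterministic sub-micrometre symmetry-breaking perturbation is applied
#' to the projected coordinates only, so exactly cocircular samples (e.g.
#' regular grids) triangulate consistently across neighbouring stars; the
#' output vertices keep the input coordinates.
#'
#' @param cloud a [point_cloud] with normals (N >= 3).
#' @param radius_mm neighbour search radius; `NULL` or 0 derives three
#'   times the median 6th-nearest-neighbour distance from the data (about
#'   four mean point spacings, enough to cover the Delaunay stars of
#'   Poisson-like samplings).
#' @param mu multiplier on the local point spacing capping neighbour
#'   distance (default 2.5).
#' @param max_angle_deg maximum normal deviation between connected points
#'   (default 120).
#' @param k maximum neighbours per star (default 36).
#' @param min_tri_angle_deg faces with a smaller minimum interior angle are
#'   discarded as slivers (default 0.5).
#' @param circum_mult candidate faces whose projected circumradius exceeds
#'   `circum_mult * radius_mm` are dropped before voting; rim slivers of a
#'   truncated neighbourhood have large empty circles and this is what
#'   removes them (default 0.6).
#' @param vote_min number of vertex stars (out of 3) that must agree on a
#'   face (default 2).
#' @return A [grain_mesh] whose vertex pool is the full input cloud;
#'   attribute `"coverage"` gives the fraction of points referenced by
#'   faces.
#' @export
triangulate_surface <- function(cloud, radius_mm = NULL, mu = 2.5,
                                max_angle_deg = 120, k = 36,
                                min_tri_angle_deg = 0.5, circum_mult = 0.6,
                                vote_min = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n < 3) stop("triangulation needs at least 3 points", call. = FALSE)
  if (is.null(cloud$normals)) {
    stop("triangulation needs normals; run estimate_normals first", call. = FALSE)
  }
  p <- cloud$points
  nrm <- cloud$normals
  k <- min(as.integer(k), n - 1L)
  nn <- FNN::get.knn(p, k = k)
  if (is.null(radius_mm) || radius_mm <= 0) {
    radius_mm <- 3 * stats::median(nn$nn.dist[, min(6L, k)])
  }
  cos_max <- cos(max_angle_deg * pi / 180)
  jit <- with_local_seed(99991L, matrix(stats::runif(3 * n, -1, 1), n, 3)) *
    1e-6 * radius_mm
  pj <- p + jit

  cap <- 12L * n
  tri_a <- integer(cap); tri_b <- integer(cap); tri_c <- integer(cap)
  cnt <- 0L
  for (i in seq_len(n)) {
    d <- nn$nn.dist[i, ]
    thr <- min(radius_mm, mu * stats::median(d))
    sel <- d <= thr
    nb <- nn$nn.index[i, sel]
    if (length(nb) >= 2) {
      dots <- nrm[nb, , drop = FALSE] %*% nrm[i, ]
      nb <- nb[dots >= cos_max]
    }
    if (length(nb) < 2) next
    ids <- c(i, nb)
    # tangent basis at i
    nz <- nrm[i, ]
    ref <- if (abs(nz[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- cross3(nz, ref); u <- u / sqrt(sum(u^2))
    v <- cross3(nz, u)
    q <- sweep(pj[ids, , drop = FALSE], 2, pj[i, ])
    x2 <- as.numeric(q %*% u)
    y2 <- as.numeric(q %*% v)
    tm <- tryCatch(suppressWarnings(interp::tri.mesh(x2, y2)), error = function(e) NULL)
    if (is.null(tm)) next
    tr <- tryCatch(interp::triangles(tm)[, 1:3, drop = FALSE],
                   error = function(e) NULL)
    if (is.null(tr) || nrow(tr) == 0) next
    star <- tr[tr[, 1] == 1L | tr[, 2] == 1L | tr[, 3] == 1L, , drop = FALSE]
    if (nrow(star) == 0) next
    # drop rim slivers: faces whose projected circumcircle is larger than
    # anything the neighbourhood could certify as empty
    ax <- x2[star[, 1]]; ay <- y2[star[, 1]]
    bx <- x2[star[, 2]]; by <- y2[star[, 2]]
    cx <- x2[star[, 3]]; cy <- y2[star[, 3]]
    la <- sqrt((bx - cx)^2 + (by - cy)^2)
    lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
    lc <- sqrt((ax - bx)^2 + (ay - by)^2)
    a2 <- 0.5 * abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
    crad <- la * lb * lc / (4 * pmax(a2, 1e-300))
    star <- star[crad <= circum_mult * radius_mm, , drop = FALSE]
    if (nrow(star) == 0) next
    g <- matrix(ids[star], ncol = 3)
    if (cnt + nrow(g) > cap) {
      cap <- max(2L * cap, cnt + nrow(g))
      length(tri_a) <- cap; length(tri_b) <- cap; length(tri_c) <- cap
    }
    idx <- cnt + seq_len(nrow(g))
    srt <- t(apply(g, 1, sort))
    tri_a[idx] <- srt[, 1]; tri_b[idx] <- srt[, 2]; tri_c[idx] <- srt[, 3]
    cnt <- cnt + nrow(g)
  }
  if (cnt == 0) stop("triangulation produced no faces", call. = FALSE)
  dt <- data.table::data.table(a = tri_a[seq_len(cnt)], b = tri_b[seq_len(cnt)],
                               c = tri_c[seq_len(cnt)])
  vt <- dt[, list(n_votes = .N), by = c("a", "b", "c")]
  vt <- vt[vt[["n_votes"]] >= vote_min, ]
  if (nrow(vt) == 0) stop("no consistently voted faces", call. = FALSE)
  faces <- as.matrix(vt[, c("a", "b", "c")])
  vote_n <- vt[["n_votes"]]

  # sliver filter on the true coordinates
  ang <- triangle_min_angle(p, faces)
  keep <- ang >= min_tri_angle_deg * pi / 180
  faces <- faces[keep, , drop = FALSE]
  vote_n <- vote_n[keep]

  # manifold repair: an edge may support at most two faces
  repeat {
    v <- nrow(p)
    ekey <- cbind((pmin(faces[, 1], faces[, 2]) - 1) * as.numeric(v) + pmax(faces[, 1], faces[, 2]) - 1,
                  (pmin(faces[, 1], faces[, 3]) - 1) * as.numeric(v) + pmax(faces[, 1], faces[, 3]) - 1,
                  (pmin(faces[, 2], faces[, 3]) - 1) * as.numeric(v) + pmax(faces[, 2], faces[, 3]) - 1)
    edt <- data.table::data.table(ek = as.vector(ekey),
                                  face = rep(seq_len(nrow(faces)), 3),
                                  vote = rep(vote_n, 3))
    edt <- edt[order(edt$ek, -edt$vote, edt$face), ]
    edt[, rank := seq_len(.N), by = "ek"]
    drop_faces <- unique(edt$face[edt$rank > 2])
    if (length(drop_faces) == 0) break
    keep <- setdiff(seq_len(nrow(faces)), drop_faces)
    faces <- faces[keep, , drop = FALSE]
    vote_n <- vote_n[keep]
    if (nrow(faces) == 0) stop("manifold repair removed all faces", call. = FALSE)
  }

  # orient by vertex normals
  fn <- face_normals(p, faces)
  vn <- nrm[faces[, 1], ] + nrm[faces[, 2], ] + nrm[faces[, 3], ]
  flip <- rowSums(fn * vn) < 0
  faces[flip, 2:3] <- faces[flip, 3:2]

  mesh <- grain_mesh(p, faces)
  attr(mesh, "coverage") <- length(unique(as.vector(faces))) / n
  mesh
}

triangle_min_angle <- function(p, faces) {
  e1 <- p[faces[, 2], , drop = FALSE] - p[faces[, 1], , drop = FALSE]
  e2 <- p[faces[, 3], , drop = FALSE] - p[faces[, 2], , drop = FALSE]
  e3 <- p[faces[, 1], , drop = FALSE] - p[faces[, 3], , drop = FALSE]
  a <- sqrt(rowSums(e2^2)); b <- sqrt(rowSums(e3^2)); c3 <- sqrt(rowSums(e1^2))
  ca <- pmin(1, pmax(-1, (b^2 + c3^2 - a^2) / (2 * b * c3)))
  cb <- pmin(1, pmax(-1, (a^2 + c3^2 - b^2) / (2 * a * c3)))
  cc <- pmin(1, pmax(-1, (a^2 + b^2 - c3^2) / (2 * a * b)))
  pmin(acos(ca), acos(cb), acos(cc))
}

face_normals <- function(p, faces) {
  u <- p[faces[, 2], , drop = FALSE] - p[faces[, 1], , drop = FALSE]
  v <- p[faces[, 3], , drop = FALSE] - p[faces[, 1], , drop = FALSE]
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Fill boundary holes with centroid fans
#'
#' Every boundary loop is closed by one new vertex at the loop centroid
#' and a triangle fan, oriented consistently with the adjacent faces.
#' Loops longer than `loop_cap` edges (e.g. a large stage-contact opening)
#' are still fanned but trigger a warning, since a fan is a coarse patch
#' for a large opening.
#'
#' @param mesh a [grain_mesh].
#' @param loop_cap loop length above which a warning is raised (default 200).
#' @return A closed (or less open) [grain_mesh]; a closed input is
#'   returned unchanged.
#' @export
fill_holes <- function(mesh, loop_cap = 200) {
  stopifnot(inherits(mesh, "grain_mesh"))
  if (nrow(mesh$faces) == 0) return(mesh)
  et <- mesh_edge_table(mesh)
  cnt <- et[, list(n = .N), by = "ek"]
  if (any(cnt$n > 2)) {
    stop("non-manifold mesh: an edge has more than two incident faces", call. = FALSE)
  }
  open_keys <- cnt$ek[cnt$n == 1]
  if (length(open_keys) == 0) return(mesh)

  # directed boundary edges, reversed w.r.t. their face orientation
  f <- mesh$faces
  dir_a <- c(f[, 1], f[, 2], f[, 3])
  dir_b <- c(f[, 2], f[, 3], f[, 1])
  v <- nrow(mesh$vertices)
  dkey <- (pmin(dir_a, dir_b) - 1) * as.numeric(v) + pmax(dir_a, dir_b) - 1
  sel <- dkey %in% open_keys
  # face holds a->b; the fill must traverse b->a
  from <- dir_b[sel]
  to <- dir_a[sel]

  verts <- mesh$vertices
  new_faces <- list()
  loops <- trace_cycles(from, to)
  for (loop in loops) {
    if (length(loop) > loop_cap) {
      warning(sprintf("boundary loop with %d edges exceeds the cap of %d; fanned anyway",
                      length(loop), loop_cap), call. = FALSE)
    }
    ctr <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, ctr)
    cvi <- nrow(verts)
    nxt_v <- c(loop[-1], loop[1])
    new_faces[[length(new_faces) + 1]] <- cbind(loop, nxt_v, cvi)
  }
  if (length(new_faces) == 0) return(mesh)
  out <- grain_mesh(verts, rbind(f, do.call(rbind, new_faces)))
  attr(out, "coverage") <- attr(mesh, "coverage")
  out
}

# Trace directed edges (from[i] -> to[i]) into simple vertex cycles.
# Walks through pinched vertices are figure-eights and are split into
# simple cycles; open chains are discarded. Cycles shorter than 3
# vertices are dropped.
trace_cycles <- function(from, to) {
  used <- logical(length(from))
  loops <- list()
  for (start in seq_along(from)) {
    if (used[start]) next
    walk <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      walk <- c(walk, from[cur])
      nxt <- which(!used & from == to[cur])
      if (length(nxt) == 0) break
      cur <- nxt[1]
    }
    if (length(walk) < 3 || to[cur] != walk[1]) next
    stack <- integer(0)
    for (v0 in walk) {
      j <- match(v0, stack)
      if (!is.na(j)) {
        sub <- stack[j:length(stack)]
        if (length(sub) >= 3) loops[[length(loops) + 1]] <- sub
        stack <- stack[seq_len(j - 1)]
      }
      stack <- c(stack, v0)
    }
    if (length(stack) >= 3) loops[[length(loops) + 1]] <- stack
  }
  loops
}

#' Close a mesh by repeated filling and erosion
#'
#' Runs [fill_holes()]; if a boundary remains (pinched or inconsistent
#' loops that a single fan pass cannot close), the faces touching the
#' remaining boundary are eroded and filling is retried, up to `max_iter`
#' rounds.
#'
#' @param mesh a [grain_mesh].
#' @param max_iter maximum erode-and-fill rounds (default 5).
#' @return A closed [grain_mesh], or an error if the boundary cannot be
#'   resolved.
#' @export
close_mesh <- function(mesh, max_iter = 5) {
  for (it in seq_len(max_iter)) {
    mesh <- fill_holes(mesh)
    be <- boundary_edges(mesh)
    if (nrow(be) == 0) return(mesh)
    v <- nrow(mesh$vertices)
    bad_keys <- (pmin(be[, 1], be[, 2]) - 1) * as.numeric(v) +
      pmax(be[, 1], be[, 2]) - 1
    et <- mesh_edge_table(mesh)
    drop <- unique(et$face[et$ek %in% bad_keys])
    if (length(drop) >= nrow(mesh$faces)) break
    mesh <- grain_mesh(mesh$vertices,
                       mesh$faces[-drop, , drop = FALSE])
  }
  mesh <- fill_holes(mesh)
  if (!is_closed_mesh(mesh)) {
    stop("mesh could not be closed", call. = FALSE)
  }
  mesh
}

#' Heron-sum surface area
#'
#' The mesh surface area as the sum over faces of the Heron formula
#' `sqrt(p (p - a) (p - b) (p - c))` with `p` the half-perimeter of the
#' face's side lengths. Numerically negative radicands of degenerate
#' slivers are clamped to zero and counted in the `"slivers"` attribute.
#'
#' @param mesh a [grain_mesh].
#' @return Surface area in mm^2, with attribute `"slivers"`.
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "grain_mesh"))
  f <- mesh$faces
  if (nrow(f) == 0) return(structure(0, slivers = 0L))
  p <- mesh$vertices
  a <- sqrt(rowSums((p[f[, 2], , drop = FALSE] - p[f[, 1], , drop = FALSE])^2))
  b <- sqrt(rowSums((p[f[, 3], , drop = FALSE] - p[f[, 2], , drop = FALSE])^2))
  c3 <- sqrt(rowSums((p[f[, 1], , drop = FALSE] - p[f[, 3], , drop = FALSE])^2))
  s <- (a + b + c3) / 2
  rad <- s * (s - a) * (s - b) * (s - c3)
  neg <- rad < 0
  rad[neg] <- 0
  structure(sum(sqrt(rad)), slivers = sum(neg))
}

#' Prism-projection volume
#'
#' The volume estimator of the trait pipeline: the mesh, expressed in the
#' grain's oriented-bounding-box frame (z along the thickness axis), is cut
#' by the central plane z = 0 through the vertex centroid; every face
#' contributes the area of its projection onto that plane times the
#' absolute height of its centre of gravity. Faces on both sides of the
#' central plane add, so the sum approximates the volume enclosed by a
#' closed surface that is star-shaped about the central plane.
#'
#' @param mesh a closed [grain_mesh] (run [fill_holes()] first).
#' @return Volume in mm^3.
#' @export
volume_prism <- function(mesh) {
  stopifnot(inherits(mesh, "grain_mesh"))
  if (!is_closed_mesh(mesh)) {
    stop("open mesh: run fill_holes before volume_prism", call. = FALSE)
  }
  f <- mesh$faces
  p <- mesh$vertices
  zc <- mean(p[unique(as.vector(f)), 3])
  x1 <- p[f[, 1], 1]; y1 <- p[f[, 1], 2]
  x2 <- p[f[, 2], 1]; y2 <- p[f[, 2], 2]
  x3 <- p[f[, 3], 1]; y3 <- p[f[, 3], 2]
  s_proj <- 0.5 * abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  h0 <- abs((p[f[, 1], 3] + p[f[, 2], 3] + p[f[, 3], 3]) / 3 - zc)
  sum(s_proj * h0)
}

#' Divergence-theorem volume
#'
#' Exact volume of a closed, consistently oriented triangle mesh as the
#' absolute sum of signed tetrahedra to the origin,
#' `|sum det(v1, v2, v3)| / 6`. Serves as the independent oracle for
#' [volume_prism()].
#'
#' @param mesh a closed [grain_mesh].
#' @return Volume in mm^3.
#' @export
volume_divergence <- function(mesh) {
  stopifnot(inherits(mesh, "grain_mesh"))
  if (!is_closed_mesh(mesh)) {
    stop("open mesh: run fill_holes before volume_divergence", call. = FALSE)
  }
  f <- mesh$faces
  p <- mesh$vertices
  v1 <- p[f[, 1], , drop = FALSE]
  v2 <- p[f[, 2], , drop = FALSE]
  v3 <- p[f[, 3], , drop = FALSE]
  det6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
    v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(det6)) / 6
}
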