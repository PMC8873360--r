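#' Analytic test solids
#'
#' Closed, consistently outward-oriented reference meshes used to validate
#' the area and volume estimators against closed-form values: an
#' axis-aligned cube, a regular tetrahedron, an icosphere (subdivided
#' icosahedron projected to the sphere) and an ellipsoid (anisotropically
#' scaled icosphere).
#'
#' @param side cube edge length.
#' @param center cube/sphere centre.
#' @return A closed [grain_mesh].
#' @export
#' @examples
#' volume_divergence(cube_mesh())      # exactly 1
#' surface_area(cube_mesh())           # exactly 6
cube_mesh <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, `+`)
  # two triangles per face of the unit-cube vertex grid
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = -h
    c(5, 6, 7), c(6, 8, 7),  # z = +h
    c(1, 2, 5), c(2, 6, 5),  # y = -h
    c(3, 7, 4), c(4, 7, 8),  # y = +h
    c(1, 5, 3), c(3, 5, 7),  # x = -h
    c(2, 4, 6), c(4, 8, 6)   # x = +h
  )
  orient_outward(grain_mesh(v, f))
}

#' @rdname cube_mesh
#' @param edge tetrahedron edge length.
#' @export
tetrahedron_mesh <- function(edge = 1) {
  s <- edge / (2 * sqrt(2))
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * s
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  orient_outward(grain_mesh(v, f))
}

#' @rdname cube_mesh
#' @param subdiv number of 4-to-1 subdivision passes (0 = icosahedron).
#' @param radius sphere radius.
#' @export
icosphere_mesh <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (it in seq_len(subdiv)) {
    res <- subdivide_once(v, f)
    v <- res$v
    f <- res$f
    v <- v / sqrt(rowSums(v^2))
  }
  orient_outward(grain_mesh(v * radius, f))
}

subdivide_once <- function(v, f) {
  nv <- nrow(v)
  midpoint_key <- function(a, b) (pmin(a, b) - 1) * nv + pmax(a, b) - 1
  keys <- c(midpoint_key(f[, 1], f[, 2]),
            midpoint_key(f[, 2], f[, 3]),
            midpoint_key(f[, 3], f[, 1]))
  uk <- unique(keys)
  mid_id <- nv + match(keys, uk)
  ka <- uk %/% nv + 1
  kb <- uk %% nv + 1
  mids <- (v[ka, , drop = FALSE] + v[kb, , drop = FALSE]) / 2
  v2 <- rbind(v, mids)
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(v = v2, f = f2)
}

#' @rdname cube_mesh
#' @param axes ellipsoid semi-axes (a, b, c).
#' @export
ellipsoid_mesh <- function(axes = c(4, 1.5, 1), subdiv = 3) {
  sph <- icosphere_mesh(subdiv, 1)
  orient_outward(grain_mesh(sweep(sph$vertices, 2, axes, `*`), sph$faces))
}

# flip faces whose normal points towards the centroid; valid for the
# convex/star-shaped fixtures above
orient_outward <- function(mesh) {
  p <- mesh$vertices
  f <- mesh$faces
  ctr <- colMeans(p)
  fn <- face_normals(p, f)
  fc <- (p[f[, 1], , drop = FALSE] + p[f[, 2], , drop = FALSE] +
           p[f[, 3], , drop = FALSE]) / 3
  flip <- rowSums(fn * sweep(fc, 2, ctr)) < 0
  f[flip, 2:3] <- f[flip, 3:2]
  grain_mesh(p, f)
}
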