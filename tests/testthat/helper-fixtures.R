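# Geometry fixtures built in code; all deterministic.

# planar grid of n x n points with pitch `by`, at height z
grid_cloud <- function(n = 10, by = 1, z = 0) {
  g <- expand.grid(x = seq_len(n) * by, y = seq_len(n) * by)
  point_cloud(cbind(g$x, g$y, z))
}

# dense uniform sample of an axis-aligned box [0, dims]
box_cloud <- function(dims = c(8, 3, 2), n = 4000, seed = 1) {
  withr::with_seed(seed, {
    point_cloud(cbind(runif(n, 0, dims[1]), runif(n, 0, dims[2]),
                      runif(n, 0, dims[3])))
  })
}

# deterministic rotation matrix from an axis-angle
rot3 <- function(axis = c(1, 2, 3), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}

# noise-free sphere sample with exact radial normals
sphere_cloud <- function(n = 3000, r = 10, seed = 1) {
  make_sphere_cloud(r, n, 0, seed)
}

# a complete trait table row set with exact internal consistency, for I/O tests
fake_trait_objects <- function(n = 2) {
  lapply(seq_len(n), function(i) {
    l <- 8 + i; w <- 3; h <- 2; V <- 20 + i; S <- 50 + i
    pr <- list(c(8, 4.5), c(16, 12), c(18, 15))  # C, S per section
    tv <- c(l = l, w = w, h = h, V = V, S = S,
            C_yz = pr[[1]][1], S_yz = pr[[1]][2],
            C_xz = pr[[2]][1], S_xz = pr[[2]][2],
            C_xy = pr[[3]][1], S_xy = pr[[3]][2],
            l_w = l / w, l_h = l / h, w_h = w / h, V_obb = l * w * h,
            S_V = S / V, S_l = S / l, S_w = S / w, S_h = S / h,
            V_l = V / l, V_w = V / w, V_h = V / h,
            c_yz = compactness(pr[[1]][1], pr[[1]][2]),
            c_xz = compactness(pr[[2]][1], pr[[2]][2]),
            c_xy = compactness(pr[[3]][1], pr[[3]][2]))
    structure(list(grain_id = i, traits = tv[trait_names()], box = NULL,
                   mesh = NULL), class = "grain_traits")
  })
}

# two Gaussian clusters whose centres differ by `sep` standard deviations
# along every trait, so the separation is visible to axis-aligned and
# metric classifiers alike
cluster_data <- function(n = 200, p = 25, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c("filled", "unfilled"), each = n / 2)
    x[y == "unfilled", ] <- x[y == "unfilled", ] + sep
    colnames(x) <- trait_names()[seq_len(p)]
    list(x = x, y = y)
  })
}
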