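#' Pipeline run configuration
#'
#' Collects every tunable parameter of the processing chain with its default.
#' The stage-plane distance threshold and the region-growing cluster size
#' range are the two knobs a bench scientist is expected to adjust per
#' scanner setup; the rest are conventions of this implementation.
#'
#' Fields (all lengths in millimetres):
#' \describe{
#'   \item{voxel_leaf_mm}{voxel edge for gravity-centre downsampling
#'     (default 0.15, just under the scanner point spacing).}
#'   \item{outlier_k}{neighbourhood size of the statistical outlier filter
#'     (default 50).}
#'   \item{outlier_std_mult}{standard-deviation multiplier of the filter
#'     threshold (default 1.0).}
#'   \item{plane_dist_mm}{RANSAC point-plane inlier distance (default 0.2).}
#'   \item{plane_margin_mm}{clearance above the fitted stage plane below
#'     which points are discarded with it (default 0.5).}
#'   \item{ransac_iters, ransac_seed}{RANSAC hypothesis count and RNG seed.}
#'   \item{normal_k}{neighbourhood size for normal/curvature estimation
#'     (default 30).}
#'   \item{rg_k}{region-growing neighbourhood size (default 30).}
#'   \item{rg_normal_angle_deg}{region-growing normal-angle threshold
#'     (default 30; grains are isolated on the stage, so the threshold
#'     only needs to keep each grain connected across its own curvature,
#'     and at scan spacing the normals of adjacent points on the sharp
#'     thickness edge of a rice grain already differ by about 15
#'     degrees).}
#'   \item{rg_curvature_max}{curvature above which a joined point stops
#'     seeding further growth (default 0.20, above the noise floor of the
#'     surface-variation estimate on scanner-noise data; a tighter gate
#'     strands the far side of the sharp grain edges).}
#'   \item{rg_min_points, rg_max_points}{accepted cluster size range
#'     (defaults 200 and 200000).}
#'   \item{mesh_search_radius_mm}{greedy-triangulation neighbour radius
#'     (default 0.7, about four times the scanner point spacing; pass 0 to
#'     individual mesh calls to derive it from the data).}
#'   \item{mesh_mu}{multiplier on the local point spacing capping neighbour
#'     distance during triangulation (default 2.5).}
#'   \item{mesh_max_angle_deg}{maximum normal deviation between a point and
#'     a triangulation neighbour (default 120).}
#'   \item{projection_alpha_mult}{multiplier on the median 2D nearest
#'     neighbour spacing used as the longest-edge cutoff of the concave-hull
#'     filter in planar projections (default 3.0).}
#' }
#'
#' @param ... named overrides of the defaults above.
#' @return A named list with class `grain_config`.
#' @export
#' @examples
#' cfg <- grain_config(plane_dist_mm = 0.3)
#' cfg$plane_dist_mm
grain_config <- function(...) {
  cfg <- list(
    voxel_leaf_mm = 0.15,
    outlier_k = 50L,
    outlier_std_mult = 1.0,
    plane_dist_mm = 0.2,
    plane_margin_mm = 0.5,
    ransac_iters = 200L,
    ransac_seed = 1L,
    normal_k = 30L,
    rg_k = 30L,
    rg_normal_angle_deg = 30,
    rg_curvature_max = 0.20,
    rg_min_points = 200L,
    rg_max_points = 200000L,
    mesh_search_radius_mm = 0.7,
    mesh_mu = 2.5,
    mesh_max_angle_deg = 120,
    projection_alpha_mult = 3.0
  )
  override <- list(...)
  if (length(override) > 0) {
    if (is.null(names(override)) || any(names(override) == "")) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown) > 0) {
      warning(sprintf("ignoring unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
      override <- override[setdiff(names(override), unknown)]
    }
    cfg[names(override)] <- override
  }
  validate_config(cfg)
  structure(cfg, class = "grain_config")
}

validate_config <- function(cfg) {
  num <- vapply(cfg, function(x) as.numeric(x)[1], numeric(1))
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad) > 0) {
    stop(sprintf("configuration value(s) must be strictly positive: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (cfg$rg_min_points >= cfg$rg_max_points) {
    stop("`rg_min_points` must be smaller than `rg_max_points`", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration file
#'
#' Accepts either a JSON object or a flat `key = value` / `key: value` text
#' file. Keys not known to [grain_config()] produce a warning and are
#' dropped; missing keys take the defaults.
#'
#' @param path file path.
#' @return A `grain_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  vals <- if (grepl("^\\s*\\{", joined)) {
    jsonlite::fromJSON(joined, simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.+)$", lines))
    bad <- which(vapply(kv, length, integer(1)) != 3)
    if (length(bad) > 0) {
      stop(sprintf("cannot parse config line %d: '%s'", bad[1], lines[bad[1]]),
           call. = FALSE)
    }
    stats::setNames(lapply(kv, function(m) utils::type.convert(m[3], as.is = TRUE)),
                    vapply(kv, `[`, character(1), 2))
  }
  do.call(grain_config, as.list(vals))
}
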