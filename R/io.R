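#' Read a point cloud from PLY, PCD or XYZ
#'
#' Coordinates are passed through unchanged and assumed to be millimetres
#' (scanner exports carry no unit metadata). PLY and PCD are supported in
#' both ASCII and binary little-endian dialects; XYZ is whitespace-separated
#' ASCII with three coordinate columns and, optionally, three normal
#' columns. An empty file yields an empty cloud rather than an error.
#'
#' @param path file path.
#' @param format `"ply"`, `"pcd"`, `"xyz"` or `"auto"` (resolve from the
#'   file extension).
#' @return A [point_cloud] with `frame = "scanner"`, points in file order.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "pcd", "xyz", "txt")) {
      stop(sprintf("cannot resolve point cloud format from extension '.%s'", ext),
           call. = FALSE)
    }
    format <- if (ext == "txt") "xyz" else ext
  }
  switch(format,
         ply = read_ply(path),
         pcd = read_pcd(path),
         xyz = read_xyz(path))
}

#' Write a point cloud to PLY, PCD or XYZ
#'
#' Round-tripping through any supported format preserves coordinates to
#' better than 1e-6 mm. PLY and PCD carry normals and curvature when
#' present; the XYZ format stores coordinates only, so normals are
#' discarded on write.
#'
#' @param cloud a [point_cloud].
#' @param path destination path (parent directory must exist).
#' @param format `"ply"`, `"pcd"` or `"xyz"`.
#' @param binary write the binary little-endian dialect (PLY/PCD only).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("ply", "pcd", "xyz"),
                              binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  switch(format,
         ply = write_ply(cloud, path, binary),
         pcd = write_pcd(cloud, path, binary),
         xyz = write_xyz(cloud, path))
  invisible(path)
}

# ---- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  toks <- strsplit(lines, "[ \t,]+")
  ncols <- lengths(toks)
  if (any(!ncols %in% c(3L, 6L, 7L))) {
    bad <- which(!ncols %in% c(3L, 6L, 7L))[1]
    stop(sprintf("malformed xyz record at line %d: expected 3, 6 or 7 columns, got %d",
                 bad, ncols[bad]), call. = FALSE)
  }
  if (length(unique(ncols)) != 1) {
    stop("inconsistent column counts in xyz file", call. = FALSE)
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad) > 0) {
    stop(sprintf("malformed xyz record at line %d: non-numeric field", bad[1]),
         call. = FALSE)
  }
  m <- do.call(rbind, vals)
  pts <- m[, 1:3, drop = FALSE]
  nrm <- if (ncol(m) >= 6) m[, 4:6, drop = FALSE] else NULL
  crv <- if (ncol(m) >= 7) m[, 7] else NULL
  point_cloud(pts, nrm, crv, frame = "scanner")
}

write_xyz <- function(cloud, path) {
  m <- cloud$points
  writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), path)
}

# ---- PLY ------------------------------------------------------------------

ply_fields <- function(cloud) {
  f <- c("x", "y", "z")
  if (!is.null(cloud$normals)) f <- c(f, "nx", "ny", "nz")
  if (!is.null(cloud$curvature)) f <- c(f, "curvature")
  f
}

cloud_field_matrix <- function(cloud) {
  m <- cloud$points
  if (!is.null(cloud$normals)) m <- cbind(m, cloud$normals)
  if (!is.null(cloud$curvature)) m <- cbind(m, cloud$curvature)
  m
}

matrix_to_cloud <- function(m, fields) {
  idx <- function(nm) match(nm, fields)
  need <- c("x", "y", "z")
  if (any(is.na(idx(need)))) stop("point cloud file lacks x/y/z fields", call. = FALSE)
  pts <- m[, idx(need), drop = FALSE]
  nrm <- NULL
  crv <- NULL
  nfields <- list(c("nx", "ny", "nz"), c("normal_x", "normal_y", "normal_z"))
  for (nf in nfields) {
    if (all(!is.na(idx(nf)))) {
      nrm <- m[, idx(nf), drop = FALSE]
      break
    }
  }
  if (!is.null(nrm) && !is.na(idx("curvature"))) crv <- m[, idx("curvature")]
  point_cloud(pts, nrm, crv, frame = "scanner")
}

write_ply <- function(cloud, path, binary) {
  fields <- ply_fields(cloud)
  m <- cloud_field_matrix(cloud)
  hdr <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment grain3d point cloud",
    sprintf("element vertex %d", nrow(m)),
    sprintf("property double %s", fields),
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    if (nrow(m) > 0) writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (nrow(m) > 0) {
      writeLines(apply(m, 1, function(r) paste(sprintf("%.7f", r), collapse = " ")),
                 con)
    }
  }
}

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY: no end_header", call. = FALSE)
    hdr <- c(hdr, line)
    if (trimws(line) == "end_header") break
    if (length(hdr) > 1000) stop("malformed PLY header", call. = FALSE)
  }
  if (trimws(hdr[1]) != "ply") stop("not a PLY file (missing 'ply' magic)", call. = FALSE)
  fmt_line <- grep("^format", hdr, value = TRUE)
  if (length(fmt_line) != 1) stop("malformed PLY: missing format line", call. = FALSE)
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line)) {
    stop("unsupported PLY format (only ascii and binary_little_endian)", call. = FALSE)
  }
  # parse elements/properties
  elements <- list()
  cur <- NULL
  for (line in hdr) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) == 0) next
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]),
                  types = character(0), names = character(0), lists = logical(0))
    } else if (toks[1] == "property" && !is.null(cur)) {
      if (toks[2] == "list") {
        cur$types <- c(cur$types, paste(toks[3], toks[4]))
        cur$names <- c(cur$names, toks[length(toks)])
        cur$lists <- c(cur$lists, TRUE)
      } else {
        cur$types <- c(cur$types, toks[2])
        cur$names <- c(cur$names, toks[3])
        cur$lists <- c(cur$lists, FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element", call. = FALSE)
  ve <- elements$vertex
  if (any(ve$lists)) stop("list properties on vertex element are unsupported", call. = FALSE)
  if (ve$count == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))

  if (binary) {
    if (names(elements)[1] != "vertex") {
      stop("binary PLY with elements before 'vertex' is unsupported", call. = FALSE)
    }
    sizes <- ply_type_size[ve$types]
    if (any(is.na(sizes))) stop("unknown PLY property type", call. = FALSE)
    raw <- readBin(con, "raw", n = ve$count * sum(sizes))
    if (length(raw) < ve$count * sum(sizes)) {
      stop("truncated binary PLY vertex data", call. = FALSE)
    }
    m <- matrix(0, ve$count, length(ve$names))
    offs <- cumsum(c(0, sizes))
    stride <- sum(sizes)
    for (j in seq_along(ve$names)) {
      byte_idx <- as.vector(outer(seq_len(sizes[j]), offs[j] + stride * (seq_len(ve$count) - 1), "+"))
      col_raw <- raw[byte_idx]
      ty <- ve$types[j]
      m[, j] <- if (ty %in% c("float", "float32", "double", "float64")) {
        readBin(col_raw, "double", n = ve$count, size = sizes[j], endian = "little")
      } else {
        readBin(col_raw, "integer", n = ve$count, size = sizes[j], endian = "little",
                signed = !startsWith(ty, "u"))
      }
    }
  } else {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < ve$count) stop("truncated ASCII PLY vertex data", call. = FALSE)
    toks <- strsplit(trimws(txt[seq_len(ve$count)]), "\\s+")
    nprop <- length(ve$names)
    bad <- which(lengths(toks) != nprop)
    if (length(bad) > 0) {
      stop(sprintf("malformed PLY vertex record %d: expected %d fields",
                   bad[1], nprop), call. = FALSE)
    }
    m <- do.call(rbind, lapply(toks, as.numeric))
    if (any(is.na(m))) stop("non-numeric PLY vertex field", call. = FALSE)
  }
  colnames(m) <- NULL
  matrix_to_cloud(m, ve$names)
}

# ---- PCD ------------------------------------------------------------------

write_pcd <- function(cloud, path, binary) {
  fields <- ply_fields(cloud)
  fields[fields %in% c("nx", "ny", "nz")] <-
    c("normal_x", "normal_y", "normal_z")[match(fields[fields %in% c("nx", "ny", "nz")],
                                                c("nx", "ny", "nz"))]
  m <- cloud_field_matrix(cloud)
  n <- nrow(m)
  hdr <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    paste("FIELDS", paste(fields, collapse = " ")),
    paste("SIZE", paste(rep(8, length(fields)), collapse = " ")),
    paste("TYPE", paste(rep("F", length(fields)), collapse = " ")),
    paste("COUNT", paste(rep(1, length(fields)), collapse = " ")),
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    sprintf("DATA %s", if (binary) "binary" else "ascii")
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    if (n > 0) writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0) {
      writeLines(apply(m, 1, function(r) paste(sprintf("%.7f", r), collapse = " ")),
                 con)
    }
  }
}

read_pcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) {
      if (is.null(hdr$FIELDS)) return(point_cloud(matrix(numeric(0), ncol = 3)))
      stop("malformed PCD: no DATA line", call. = FALSE)
    }
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- strsplit(line, "\\s+")[[1]]
    hdr[[toks[1]]] <- toks[-1]
    if (toks[1] == "DATA") break
  }
  fields <- hdr$FIELDS
  if (is.null(fields)) stop("malformed PCD: missing FIELDS", call. = FALSE)
  n <- as.integer(hdr$POINTS[1])
  if (is.na(n)) stop("malformed PCD: missing POINTS", call. = FALSE)
  if (n == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  sizes <- as.integer(hdr$SIZE)
  types <- hdr$TYPE
  mode <- hdr$DATA[1]
  if (mode == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < n) stop("truncated PCD data", call. = FALSE)
    toks <- strsplit(trimws(txt[seq_len(n)]), "\\s+")
    bad <- which(lengths(toks) != length(fields))
    if (length(bad) > 0) {
      stop(sprintf("malformed PCD record %d: expected %d fields", bad[1],
                   length(fields)), call. = FALSE)
    }
    m <- do.call(rbind, lapply(toks, as.numeric))
    if (any(is.na(m))) stop("non-numeric PCD field", call. = FALSE)
  } else if (mode == "binary") {
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride) stop("truncated binary PCD data", call. = FALSE)
    m <- matrix(0, n, length(fields))
    offs <- cumsum(c(0, sizes))
    for (j in seq_along(fields)) {
      byte_idx <- as.vector(outer(seq_len(sizes[j]), offs[j] + stride * (seq_len(n) - 1), "+"))
      col_raw <- raw[byte_idx]
      m[, j] <- if (types[j] == "F") {
        readBin(col_raw, "double", n = n, size = sizes[j], endian = "little")
      } else {
        readBin(col_raw, "integer", n = n, size = sizes[j], endian = "little",
                signed = types[j] != "U")
      }
    }
  } else {
    stop(sprintf("unsupported PCD DATA mode '%s'", mode), call. = FALSE)
  }
  matrix_to_cloud(m, fields)
}

# ---- trait tables ---------------------------------------------------------

#' Canonical trait names
#'
#' The 25 trait columns in their fixed table order: length `l`, width `w`,
#' thickness `h`, volume `V`, surface area `S`; perimeter and area of the
#' cross (`C_yz`, `S_yz`), longitudinal (`C_xz`, `S_xz`) and horizontal
#' (`C_xy`, `S_xy`) sections; the ratios `l_w`, `l_h`, `w_h`; bounding-box
#' volume `V_obb`; specific surface area `S_V`; surface-area ratios `S_l`,
#' `S_w`, `S_h`; volume ratios `V_l`, `V_w`, `V_h`; and the compactness
#' indices `c_yz`, `c_xz`, `c_xy` of the three sections.
#'
#' @return Character vector of length 25.
#' @export
trait_names <- function() {
  c("l", "w", "h", "V", "S",
    "C_yz", "S_yz", "C_xz", "S_xz", "C_xy", "S_xy",
    "l_w", "l_h", "w_h", "V_obb",
    "S_V", "S_l", "S_w", "S_h",
    "V_l", "V_w", "V_h",
    "c_yz", "c_xz", "c_xy")
}

#' Write a trait table to CSV
#'
#' One row per grain, a `grain_id` column first and then the 25 canonical
#' trait columns in [trait_names()] order.
#'
#' @param traits a list of trait vectors as returned by [compute_traits()],
#'   or a data frame already in table layout.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  df <- as_trait_table(traits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_trait_table <- function(traits) {
  if (is.data.frame(traits)) {
    missing_cols <- setdiff(c("grain_id", trait_names()), names(traits))
    if (length(missing_cols) > 0) {
      stop(sprintf("trait table lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    return(traits[, c("grain_id", trait_names())])
  }
  if (inherits(traits, "grain_traits")) traits <- list(traits)
  rows <- lapply(traits, function(tv) {
    vals <- tv$traits
    if (!all(trait_names() %in% names(vals))) {
      stop("incomplete trait vector: all 25 traits are required", call. = FALSE)
    }
    cbind(data.frame(grain_id = tv$grain_id), as.data.frame(t(vals[trait_names()])))
  })
  do.call(rbind, rows)
}

#' Read a trait table CSV
#' @param path CSV produced by [write_trait_table()] (extra columns such as
#'   a class label are carried through).
#' @return A data frame with `grain_id` and the 25 trait columns.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, check.names = FALSE)
}
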