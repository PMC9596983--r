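#' Read and write centerline curves
#'
#' Curves travel as plain CSV (columns `x,y,z`, one point per row, header
#' line, mm) or as VTK legacy ASCII polyline files (`DATASET POLYDATA` with a
#' single `LINES` cell). Both round-trip through [new_vt_curve()] validation.
#'
#' @param curve A `vt_curve` or data frame with `x`, `y`, `z` columns.
#' @param path File path.
#' @return `write_curve_csv()`/`write_curve_vtk()` return `path` invisibly;
#'   the readers return a `vt_curve`.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve_matrix(curve))
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("Curve CSV must have columns x, y, z.", call. = FALSE)
  }
  new_vt_curve(df[, c("x", "y", "z")])
}

#' @rdname curve_io
#' @export
write_curve_vtk <- function(curve, path) {
  pts <- curve_matrix(curve)
  n <- nrow(pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel centerline", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(apply(pts, 1, function(p) paste(format(p, digits = 17), collapse = " ")), con)
  writeLines(sprintf("LINES 1 %d", n + 1L), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1) stop("Not a VTK polyline file: no POINTS block.", call. = FALSE)
  n <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  body <- lines[(ip + 1):length(lines)]
  body <- body[!grepl("^[A-Za-z]", trimws(body)) & nzchar(trimws(body))]
  coords <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  coords <- coords[!is.na(coords)]
  pts <- matrix(coords[seq_len(3L * n)], ncol = 3, byrow = TRUE)
  il <- grep("^LINES", lines)
  if (length(il) == 1) {
    idx <- as.integer(strsplit(trimws(lines[il + 1L]), "\\s+")[[1]])
    ord <- idx[-1] + 1L
    pts <- pts[ord, , drop = FALSE]
  }
  new_vt_curve(pts)
}

#' Read and write tubular surface meshes
#'
#' Minimal readers/writers for the triangle-mesh formats the synthetic-data
#' generator uses: PLY and STL (ASCII by default, binary little-endian via
#' `binary = TRUE`) and ASCII OFF (read only). STL stores no vertex indices,
#' so `read_mesh()` on an STL merges coincident vertices before validation.
#'
#' @param mesh A `vt_mesh` (see [make_tube_mesh()]).
#' @param path File path; the extension (`.ply`, `.stl`, `.off`) picks the
#'   format.
#' @param binary Write the binary flavour of PLY/STL instead of ASCII.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` a `vt_mesh`.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "vt_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary),
    stl = write_stl(mesh, path, binary),
    stop("Unsupported mesh format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    off = read_off(path),
    stop("Unsupported mesh format: .", ext, call. = FALSE)
  )
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(v, 1, function(p) paste(format(p, digits = 17), collapse = " ")), con)
    writeLines(apply(f, 1, function(tri) paste(c(3L, tri - 1L), collapse = " ")), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 200) stop("Malformed PLY header.", call. = FALSE)
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  binary <- any(grepl("binary_little_endian", hdr))
  if (binary) {
    v <- matrix(readBin(con, "double", 3L * nv, size = 8, endian = "little"),
                ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      k <- as.integer(readBin(con, "raw", 1))
      f[i, ] <- readBin(con, "integer", k, size = 4, endian = "little") + 1L
    }
  } else {
    body <- readLines(con)
    vtx <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    v <- matrix(as.numeric(unlist(vtx)), ncol = 3, byrow = TRUE)
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    f <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  }
  new_vt_mesh(v, f)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals(v, f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(nrm[i, ], t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vesseltort", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.17g %.17g %.17g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vesseltort", con)
  }
}

read_stl <- function(path) {
  con <- file(path, "rb")
  probe <- readBin(con, "raw", 5)
  close(con)
  if (rawToChar(probe) == "solid" && any(grepl("facet", readLines(path, n = 20)))) {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                              function(x) x[2:4]))),
                     ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(0, 3L * nf, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      coords[3L * i - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  # STL repeats vertices per facet; merge exact duplicates to recover indices
  key <- apply(signif(coords, 12), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  v <- coords[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  new_vt_mesh(v, f)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("Not an OFF file.", call. = FALSE)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(as.numeric(unlist(strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+"))),
              ncol = 3, byrow = TRUE)
  fl <- strsplit(trimws(lines[2 + nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  new_vt_mesh(v, f)
}

#' Read and write cohort tables
#'
#' Cohorts are CSV files with one row per patient; the outcome columns `iss`
#' and `co` are mandatory and must be 0/1.
#'
#' @param cohort A cohort tibble (see [make_cohort()]).
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(all(c("iss", "co") %in% names(cohort)))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("iss", "co") %in% names(df))) {
    stop("Cohort CSV must contain `iss` and `co` columns.", call. = FALSE)
  }
  for (col in c("iss", "co")) {
    if (!all(df[[col]] %in% c(0, 1))) {
      stop("Column `", col, "` must be binary 0/1.", call. = FALSE)
    }
  }
  df
}

#' Write tortuosity metrics and geometry profiles
#'
#' Metrics go out as a one-row CSV with the canonical column names
#' (`mean_curvature`, `max_curvature`, `range_curvature`, `mean_torsion`,
#' `max_torsion`, `range_torsion`, `DM`, `L`, `l`); profiles as a CSV of
#' arc-length position `s` with `kappa` and `tau`.
#'
#' @param metrics One-row tibble from [tortuosity_metrics()].
#' @param profile Tibble from [geometry_profile()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("mean_curvature", "max_curvature", "range_curvature",
            "mean_torsion", "max_torsion", "range_torsion", "DM", "L", "l")
  utils::write.csv(as.data.frame(metrics)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("s", "kappa", "tau")], path,
                   row.names = FALSE)
  invisible(path)
}
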