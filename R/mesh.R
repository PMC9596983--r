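#' Triangulated tube meshes around a centerline
#'
#' `make_tube_mesh()` sweeps a circular cross-section of radius `tube_radius`
#' along a sampled curve using rotation-minimizing (parallel-transport)
#' frames, producing a triangulated tube whose cross-sections are circles
#' normal to the local tangent — the synthetic stand-in for a reconstructed
#' vessel surface. Ends are left open (two boundary rings) by default or
#' capped with triangle fans.
#'
#' The sweep is rejected when `tube_radius` is not smaller than the minimum
#' radius of curvature of the centerline, since the tube would self-intersect
#' on the inner side of the bend.
#'
#' @param curve A `vt_curve` (ordered centerline points, mm).
#' @param tube_radius Tube radius in mm.
#' @param resolution Number of vertices per cross-section ring (>= 3).
#' @param cap_ends Close the two end rings with triangle fans.
#' @return A `vt_mesh`: list with `vertices` (n x 3 matrix, mm), `faces`
#'   (m x 3 integer matrix, 1-based), and `radius` (nominal tube radius).
#' @examples
#' cl <- make_curve("line", length = 20, n_points = 30)
#' tube <- make_tube_mesh(cl, tube_radius = 2, resolution = 16)
#' @export
make_tube_mesh <- function(curve, tube_radius, resolution = 16,
                           cap_ends = FALSE) {
  pts <- curve_matrix(curve)
  n <- nrow(pts)
  if (tube_radius <= 0) stop("`tube_radius` must be positive.", call. = FALSE)
  if (resolution < 3) stop("`resolution` must be at least 3.", call. = FALSE)

  kappa_max <- polyline_max_curvature(pts)
  if (kappa_max > 0 && tube_radius >= 1 / kappa_max) {
    stop(sprintf(paste0("Tube radius %.3g is not smaller than the minimum ",
                        "radius of curvature %.3g; the tube would ",
                        "self-intersect."), tube_radius, 1 / kappa_max),
         call. = FALSE)
  }

  tangents <- exact_tangents(curve) %||% polyline_tangents(pts)
  # parallel-transport frame: rotate the previous normal by the minimal
  # rotation taking tangent i-1 to tangent i (double-reflection method)
  normals <- matrix(0, n, 3)
  normals[1, ] <- orthonormal_to(tangents[1, ])
  for (i in 2:n) {
    normals[i, ] <- transport_vector(normals[i - 1, ], tangents[i - 1, ],
                                     tangents[i, ])
  }

  theta <- 2 * pi * (seq_len(resolution) - 1L) / resolution
  verts <- matrix(0, n * resolution, 3)
  for (i in seq_len(n)) {
    b <- cross3(tangents[i, ], normals[i, ])
    ring <- pts[rep(i, resolution), ] +
      tube_radius * (cos(theta) %o% normals[i, ] + sin(theta) %o% b)
    verts[(i - 1L) * resolution + seq_len(resolution), ] <- ring
  }

  faces <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a0 <- (i - 1L) * resolution + seq_len(resolution)
    a1 <- a0 + resolution
    nxt <- c(seq_len(resolution)[-1], 1L)
    b0 <- (i - 1L) * resolution + nxt
    b1 <- b0 + resolution
    faces[[i]] <- rbind(cbind(a0, b0, b1), cbind(a0, b1, a1))
  }
  faces <- do.call(rbind, faces)

  if (cap_ends) {
    c1 <- nrow(verts) + 1L
    c2 <- nrow(verts) + 2L
    verts <- rbind(verts, pts[1, ], pts[n, ])
    r0 <- seq_len(resolution)
    rn <- (n - 1L) * resolution + seq_len(resolution)
    nxt <- c(r0[-1], r0[1])
    faces <- rbind(faces,
                   cbind(c1, nxt, r0),
                   cbind(c2, rn, (n - 1L) * resolution + c(seq_len(resolution)[-1], 1L)))
  }

  new_vt_mesh(verts, faces, radius = tube_radius)
}

#' Construct and validate a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param radius Optional nominal tube radius (mm).
#' @return A `vt_mesh` list.
#' @export
new_vt_mesh <- function(vertices, faces, radius = NULL) {
  v <- unname(as.matrix(vertices)); storage.mode(v) <- "double"
  f <- unname(as.matrix(faces)); storage.mode(f) <- "integer"
  if (ncol(v) != 3 || ncol(f) != 3) {
    stop("Mesh needs n x 3 vertices and m x 3 faces.", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("Mesh vertices must be finite.", call. = FALSE)
  if (any(f < 1L) || any(f > nrow(v))) {
    stop("Face indices out of range.", call. = FALSE)
  }
  structure(list(vertices = v, faces = f, radius = radius), class = "vt_mesh")
}

#' @export
print.vt_mesh <- function(x, ...) {
  cat(sprintf("<vt_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$radius)) cat(sprintf(", nominal radius %.3g mm", x$radius))
  cat("\n")
  invisible(x)
}

#' Edge-manifold check for tube meshes
#'
#' Classifies every edge by the number of incident faces. A clean open tube
#' has all interior edges shared by exactly 2 faces and its two end rings as
#' boundary edges (1 face); a capped tube has no boundary edges. Edges with
#' 3+ incident faces indicate non-manifold geometry.
#'
#' @param mesh A `vt_mesh`.
#' @return A list with counts `interior`, `boundary`, `nonmanifold` and
#'   logical `is_manifold` (no edge with > 2 faces).
#' @export
mesh_edge_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  list(interior = sum(tab == 2), boundary = sum(tab == 1),
       nonmanifold = sum(tab > 2), is_manifold = all(tab <= 2))
}

# boundary loops as ordered vertex index cycles (used to seed centerline
# extraction at the tube ends)
mesh_boundary_loops <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bnd <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  loops <- list()
  if (nrow(bnd) == 0) return(loops)
  adj <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  visited <- integer(0)
  for (start in unique(as.vector(bnd))) {
    if (start %in% visited) next
    loop <- start
    prev <- NA_integer_
    cur <- start
    repeat {
      nbrs <- setdiff(adj[[as.character(cur)]], prev)
      if (length(nbrs) == 0) break
      nxt <- nbrs[1]
      if (nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
      if (length(loop) > nrow(bnd)) break
    }
    visited <- c(visited, loop)
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("Cannot normalize a zero vector.", call. = FALSE)
  v / n
}

orthonormal_to <- function(t) {
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(ref - sum(ref * t) * t)
}

# minimal rotation of `v` taking unit tangent t0 to t1 (Rodrigues)
transport_vector <- function(v, t0, t1) {
  axis <- cross3(t0, t1)
  s <- sqrt(sum(axis^2))
  c_ <- sum(t0 * t1)
  if (s < 1e-14) {
    out <- if (c_ > 0) v else -v
  } else {
    k <- axis / s
    out <- v * c_ + cross3(k, v) * s + k * sum(k * v) * (1 - c_)
  }
  # re-orthogonalize against the new tangent to stop drift
  unit3(out - sum(out * t1) * t1)
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  tg[1, ] <- unit3(pts[2, ] - pts[1, ])
  tg[n, ] <- unit3(pts[n, ] - pts[n - 1, ])
  if (n > 2) {
    for (i in 2:(n - 1)) tg[i, ] <- unit3(pts[i + 1, ] - pts[i - 1, ])
  }
  tg
}

# closed-form unit tangents when the curve came from a noiseless known
# family; NULL otherwise (falls back to finite differences)
exact_tangents <- function(curve) {
  spec <- attr(curve, "curve_spec")
  if (is.null(spec) || !isTRUE(spec$noise_sd == 0)) return(NULL)
  n <- spec$n_points
  switch(spec$family,
    line = matrix(rep(c(0, 0, 1), each = n), n, 3),
    arc = {
      t <- seq(0, spec$angle, length.out = n)
      cbind(-sin(t), cos(t), 0)
    },
    helix = {
      t <- seq(0, 2 * pi * spec$turns, length.out = n)
      sp <- sqrt(spec$a^2 + spec$b^2)
      cbind(-spec$a * sin(t) / sp, spec$a * cos(t) / sp, spec$b / sp)
    },
    NULL
  )
}

# discrete curvature upper estimate from circumradius of point triples
polyline_max_curvature <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  k <- 0
  for (i in 2:(n - 1)) {
    a <- pts[i - 1, ]; b <- pts[i, ]; c_ <- pts[i + 1, ]
    ab <- b - a; ac <- c_ - a; bc <- c_ - b
    area2 <- sqrt(sum(cross3(ab, ac)^2))
    if (area2 > 0) {
      r <- sqrt(sum(ab^2)) * sqrt(sum(ac^2)) * sqrt(sum(bc^2)) / (2 * area2)
      k <- max(k, 1 / r)
    }
  }
  k
}

face_normals <- function(v, f) {
  n1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
               n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
               n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}
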