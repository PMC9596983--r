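#' Extract the centerline of a tubular mesh
#'
#' The centerline of a vessel is the locus of centers of maximal inscribed
#' spheres along the tube. This implementation marches cutting planes along
#' the tube: starting from one end ring, each cross-section is cut with a
#' plane normal to the running tangent, and the center of the maximal
#' inscribed circle of the section polygon (its Chebyshev center) is taken as
#' the centerline point. After the first march, the tangents are re-estimated
#' from the smoothed extracted polyline and every cross-section is re-cut and
#' re-centered once, so the final planes are normal to the centerline itself.
#'
#' The mesh must be a single open-ended tube: exactly two boundary loops and
#' no non-manifold edges. Branching meshes (more than two boundary loops) and
#' degenerate meshes are rejected.
#'
#' @param mesh A `vt_mesh` (see [make_tube_mesh()] / [read_mesh()]).
#' @param step Spacing between consecutive centerline points along the tube
#'   axis, in mm. The default 0.5 mm is sub-voxel for rotational-angiography
#'   scale vessels.
#' @return A `vt_curve` of ordered centerline points running from one end of
#'   the tube to the other.
#' @examples
#' tube <- make_tube_mesh(make_curve("line", length = 20, n_points = 40),
#'                        tube_radius = 2, resolution = 16)
#' cl <- extract_centerline(tube, step = 1)
#' @export
extract_centerline <- function(mesh, step = 0.5) {
  stopifnot(inherits(mesh, "vt_mesh"))
  if (step <= 0) stop("`step` must be positive.", call. = FALSE)
  man <- mesh_edge_manifold(mesh)
  if (!man$is_manifold) {
    stop("Mesh has non-manifold edges; not a simple tube.", call. = FALSE)
  }
  loops <- mesh_boundary_loops(mesh)
  if (length(loops) > 2) {
    stop("Mesh has ", length(loops), " boundary loops; branching or ",
         "multi-channel meshes are not supported.", call. = FALSE)
  }
  if (length(loops) < 2) {
    stop("Mesh has no two open ends; cap removal or a tube with two ",
         "boundary rings is required.", call. = FALSE)
  }
  v <- mesh$vertices
  ring1 <- v[loops[[1]], , drop = FALSE]
  ring2 <- v[loops[[2]], , drop = FALSE]
  c1 <- colMeans(ring1)
  c2 <- colMeans(ring2)

  # first march: start just inside one end ring, advance plane along the
  # running tangent; sections that clip an open end do not close and stop
  # the march
  t0 <- unit3(ring_inward_normal(ring1, c2 - c1))
  pts <- march_tube(mesh, start = c1 + 0.5 * step * t0, tangent0 = t0,
                    target = c2, step = step)
  if (nrow(pts) < 4) stop("Centerline extraction failed: fewer than 4 ",
                          "cross-sections found.", call. = FALSE)

  # refinement passes: smooth the extracted polyline with a regression
  # spline, re-cut every cross-section with a plane normal to the smoothed
  # tangent, and re-center; inscribed-circle centers are very sensitive to
  # plane tilt on curved tubes, so tangents must come from a smoother, not
  # from finite differences of the raw march
  refined <- pts
  for (pass in 1:2) {
    sp <- suppressWarnings(fit_free_knot_spline(
      new_vt_curve(refined), degree = 3,
      max_interior_knots = max(4L, min(20L, nrow(refined) %/% 5L))))
    tg <- predict(sp, sp$t, deriv = 1)
    pos <- predict(sp, sp$t)
    for (i in seq_len(nrow(refined))) {
      sec <- cross_section(mesh, pos[i, ], unit3(tg[i, ]))
      if (!is.null(sec)) refined[i, ] <- sec$center
    }
  }
  new_vt_curve(refined)
}

# advance cutting planes from `start` toward `target`
march_tube <- function(mesh, start, tangent0, target, step) {
  max_steps <- ceiling(4 * sqrt(sum((target - start)^2)) / step) + 200L
  pts <- matrix(NA_real_, max_steps, 3)
  p <- start
  tg <- tangent0
  n_found <- 0L
  for (i in seq_len(max_steps)) {
    sec <- cross_section(mesh, p, tg)
    if (is.null(sec)) break
    if (n_found > 0) {
      jump <- sec$center - pts[n_found, ]
      # a long or backwards jump means the plane slid onto another part of
      # the tube (e.g. the neighbouring turn of a coiled vessel): stop here
      if (sqrt(sum(jump^2)) > 2.5 * step || sum(jump * tg) < 0) break
    }
    n_found <- n_found + 1L
    pts[n_found, ] <- sec$center
    if (n_found > 1) {
      tg_new <- unit3(pts[n_found, ] - pts[n_found - 1L, ])
      tg <- unit3(0.5 * tg + 0.5 * tg_new)  # smoothed running tangent
    }
    if (sqrt(sum((sec$center - target)^2)) < step) break
    p <- sec$center + step * tg
  }
  pts[seq_len(n_found), , drop = FALSE]
}

# cut the mesh with the plane through `origin` with normal `normal`; return
# the Chebyshev center (maximal inscribed circle) of the section loop nearest
# the origin
cross_section <- function(mesh, origin, normal) {
  v <- mesh$vertices
  f <- mesh$faces
  normal <- unit3(normal)
  d <- as.vector((v - matrix(origin, nrow(v), 3, byrow = TRUE)) %*% normal)
  side <- d > 0
  fs <- matrix(side[f], ncol = 3)
  crossing <- which(rowSums(fs) %in% c(1L, 2L))
  if (length(crossing) < 3) return(NULL)

  # each crossing triangle contributes one segment joining its two cut edges
  seg_keys <- matrix(NA_character_, length(crossing), 2)
  for (j in seq_along(crossing)) {
    tri <- f[crossing[j], ]
    e <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    cut <- side[e[, 1]] != side[e[, 2]]
    ek <- paste(pmin(e[cut, 1], e[cut, 2]), pmax(e[cut, 1], e[cut, 2]))
    seg_keys[j, ] <- ek
  }
  keys <- unique(as.vector(seg_keys))
  ij <- matrix(as.integer(unlist(strsplit(keys, " "))), ncol = 2, byrow = TRUE)
  w <- d[ij[, 1]] / (d[ij[, 1]] - d[ij[, 2]])
  ipts <- v[ij[, 1], , drop = FALSE] * (1 - w) + v[ij[, 2], , drop = FALSE] * w
  rownames(ipts) <- keys

  # walk the section segments into closed loops
  k1 <- match(seg_keys[, 1], keys)
  k2 <- match(seg_keys[, 2], keys)
  nbr <- split(c(k2, k1), c(k1, k2))  # key index -> neighbouring key indices
  used <- rep(FALSE, length(keys))
  loops <- list()
  for (start in seq_along(keys)) {
    if (used[start]) next
    loop <- start
    used[start] <- TRUE
    prev <- NA_integer_
    cur <- start
    closed <- FALSE
    repeat {
      cand_next <- nbr[[as.character(cur)]]
      if (length(loop) >= 3 && loop[1] %in% setdiff(cand_next, prev)) {
        closed <- TRUE
      }
      nx <- setdiff(cand_next, c(prev, loop[1]))
      nx <- nx[!used[nx]]
      if (length(nx) == 0) break
      prev <- cur
      cur <- nx[1]
      used[cur] <- TRUE
      loop <- c(loop, cur)
    }
    # only closed section loops are usable; open chains mean the plane ran
    # off an open end
    if (closed && length(loop) >= 3) loops[[length(loops) + 1L]] <- loop
  }
  if (length(loops) == 0) return(NULL)

  # the local channel is the loop nearest the plane origin
  dmin <- vapply(loops, function(lp) {
    min(sqrt(rowSums((ipts[lp, , drop = FALSE] -
                        matrix(origin, length(lp), 3, byrow = TRUE))^2)))
  }, numeric(1))
  loop <- loops[[which.min(dmin)]]
  sec <- ipts[loop, , drop = FALSE]

  # 2D coordinates in the plane, oriented counter-clockwise
  e1 <- orthonormal_to(normal)
  e2 <- cross3(normal, e1)
  ctr <- colMeans(sec)
  rel <- sec - matrix(ctr, nrow(sec), 3, byrow = TRUE)
  u <- rel %*% cbind(e1, e2)
  nxt <- c(seq_len(nrow(u))[-1], 1L)
  area2 <- sum(u[, 1] * u[nxt, 2] - u[nxt, 1] * u[, 2])
  if (area2 < 0) u <- u[rev(seq_len(nrow(u))), , drop = FALSE]
  cc <- chebyshev_center(u)
  start2d <- ctr + cc$center[1] * e1 + cc$center[2] * e2

  # the returned point maximizes the inscribed-SPHERE radius (3D distance to
  # the surface) over the cross-section plane: the 2D inscribed circle is
  # degenerate under plane tilt (it slides along the section's major axis),
  # the 3D sphere objective is not
  r_hint <- max(sqrt(rowSums((sec - matrix(start2d, nrow(sec), 3,
                                           byrow = TRUE))^2)))
  ms <- max_inscribed_center(mesh, start2d, normal, r_hint)
  list(center = ms$center, radius = ms$radius, n = nrow(u))
}

# maximize min distance to the mesh surface over points of the cutting plane
max_inscribed_center <- function(mesh, origin, normal, r_hint) {
  v <- mesh$vertices
  f <- mesh$faces
  d2v <- rowSums((v - matrix(origin, nrow(v), 3, byrow = TRUE))^2)
  near <- d2v < (2.5 * r_hint)^2
  cand <- which(near[f[, 1]] | near[f[, 2]] | near[f[, 3]])
  if (length(cand) == 0) cand <- seq_len(nrow(f))
  A <- v[f[cand, 1], , drop = FALSE]
  B <- v[f[cand, 2], , drop = FALSE]
  C <- v[f[cand, 3], , drop = FALSE]
  e1 <- orthonormal_to(normal)
  e2 <- cross3(normal, e1)
  fobj <- function(uv) {
    p <- origin + uv[1] * e1 + uv[2] * e2
    -min(point_triangle_dist(p, A, B, C))
  }
  res <- stats::optim(c(0, 0), fobj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 300))
  list(center = origin + res$par[1] * e1 + res$par[2] * e2,
       radius = -res$value)
}

# distance from a point to each triangle (Ericson closest-point regions),
# vectorized over triangles
point_triangle_dist <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A
  ap <- P - A; bp <- P - B; cp <- P - C
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  closest <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set <- function(mask, pts) {
    m <- mask & !done
    closest[m, ] <<- pts[m, , drop = FALSE]
    done <<- done | m
  }
  set(d1 <= 0 & d2 <= 0, A)
  set(d3 >= 0 & d4 <= d3, B)
  set(d6 >= 0 & d5 <= d6, C)
  w_ab <- d1 / pmax(d1 - d3, 1e-300)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * w_ab)
  w_ac <- d2 / pmax(d2 - d6, 1e-300)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * w_ac)
  w_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * w_bc)
  denom <- pmax(va + vb + vc, 1e-300)
  set(rep(TRUE, n), A + ab * (vb / denom) + ac * (vc / denom))
  sqrt(rowSums((P - closest)^2))
}

# maximal inscribed circle center of a planar polygon given counter-clockwise
# (inward-normal) orientation: maximize the minimum signed distance to the
# edges, polished by Nelder-Mead from the vertex centroid
chebyshev_center <- function(poly) {
  m <- nrow(poly)
  nxt <- c(seq_len(m)[-1], 1L)
  e <- poly[nxt, , drop = FALSE] - poly
  len <- sqrt(rowSums(e^2))
  ok <- len > 1e-12
  e <- e[ok, , drop = FALSE]
  p0 <- poly[ok, , drop = FALSE]
  len <- len[ok]
  nrm <- cbind(-e[, 2], e[, 1]) / len  # inward for CCW
  mindist <- function(c_) {
    min(rowSums((matrix(c_, nrow(nrm), 2, byrow = TRUE) - p0) * nrm))
  }
  start <- colMeans(poly)
  res <- stats::optim(start, function(c_) -mindist(c_), method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  list(center = res$par, radius = -res$value)
}

# inward normal of an end ring: best-fit plane normal oriented along `toward`
ring_inward_normal <- function(ring, toward) {
  rel <- ring - matrix(colMeans(ring), nrow(ring), 3, byrow = TRUE)
  nrm <- svd(rel, nu = 0)$v[, 3]
  if (sum(nrm * toward) < 0) nrm <- -nrm
  nrm
}

smooth_polyline <- function(pts, half_window = 2L) {
  n <- nrow(pts)
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_window)
    hi <- min(n, i + half_window)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

#' Clip a centerline between proximal and distal landmarks
#'
#' Projects the two landmark points onto the curve and returns the sub-curve
#' between the two projections, oriented proximal to distal. The endpoints of
#' the clipped curve are the exact projection points, interpolated between
#' samples. When `normalize_orientation` is `TRUE` (default) the output
#' always runs from the proximal projection to the distal one, regardless of
#' the direction in which the input curve was sampled.
#'
#' A landmark farther than `warn_distance` (one tube radius, when known) from
#' the curve triggers a warning, but its projection is still used.
#'
#' @param curve A `vt_curve`.
#' @param proximal,distal Numeric length-3 landmark coordinates (mm), e.g.
#'   the proximal and distal ends of an implanted stent.
#' @param normalize_orientation Reorient output proximal -> distal.
#' @param warn_distance Distance (mm) beyond which a landmark is flagged as
#'   far from the curve; `NULL` disables the check.
#' @return A `vt_curve` running between the two projection points.
#' @examples
#' cl <- make_curve("line", length = 50, n_points = 100)
#' seg <- clip_segment(cl, proximal = c(0.5, 0, 10), distal = c(0, 0.5, 40))
#' curve_chord_stats(seg)$L # 30
#' @export
clip_segment <- function(curve, proximal, distal, normalize_orientation = TRUE,
                         warn_distance = NULL) {
  pts <- curve_matrix(curve)
  pp <- project_to_polyline(pts, as.numeric(proximal))
  pd <- project_to_polyline(pts, as.numeric(distal))
  if (!is.null(warn_distance)) {
    if (pp$dist > warn_distance) {
      warning(sprintf("Proximal landmark is %.3g mm from the curve.", pp$dist),
              call. = FALSE)
    }
    if (pd$dist > warn_distance) {
      warning(sprintf("Distal landmark is %.3g mm from the curve.", pd$dist),
              call. = FALSE)
    }
  }
  if (abs(pp$s - pd$s) < 1e-12) {
    stop("Landmarks project to the same point on the curve.", call. = FALSE)
  }
  lo <- if (pp$s < pd$s) pp else pd
  hi <- if (pp$s < pd$s) pd else pp
  seg <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  inside <- which(seg > lo$s & seg < hi$s)
  out <- rbind(lo$point, pts[inside, , drop = FALSE], hi$point)
  # drop duplicated points when a projection coincides with a sample
  d <- sqrt(rowSums(diff(out)^2))
  out <- out[c(TRUE, d > 1e-12), , drop = FALSE]
  if (normalize_orientation && pp$s > pd$s) out <- out[rev(seq_len(nrow(out))), ]
  new_vt_curve(out)
}

# closest point on a polyline; returns the point, its arc-length position and
# the distance to the query
project_to_polyline <- function(pts, q) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- rowSums((matrix(q, nrow(a), 3, byrow = TRUE) - a) * ab) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  d2 <- rowSums((proj - matrix(q, nrow(a), 3, byrow = TRUE))^2)
  i <- which.min(d2)
  seg <- c(0, cumsum(sqrt(len2)))
  list(point = proj[i, ], s = seg[i] + t[i] * sqrt(len2[i]),
       dist = sqrt(d2[i]))
}
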