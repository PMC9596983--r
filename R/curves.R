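#' Synthetic 3D centerline curves with analytic ground truth
#'
#' `make_curve()` samples a parametric space curve from one of four families
#' and returns it as an ordered point set, the raw representation of a vessel
#' centerline. Where closed forms exist (line, arc, helix) the analytic
#' curvature, torsion and distance metric (DM) of the noiseless curve are
#' attached as ground truth, so downstream fitting and metric code can be
#' checked against known values.
#'
#' Families and their closed forms (all lengths in mm, curvature/torsion in
#' mm^-1):
#' * `line`: straight segment of the given `length`; kappa = tau = 0, DM = 1.
#' * `arc`: planar circular arc of radius `a` spanning `angle` radians;
#'   kappa = 1/a, tau = 0, DM = 2 sin(angle/2) / angle.
#' * `helix`: r(t) = (a cos t, a sin t, b t) over `turns` full turns;
#'   kappa = a / (a^2 + b^2), tau = b / (a^2 + b^2),
#'   DM for whole turns = b / sqrt(a^2 + b^2).
#' * `composite`: a line, arc and helix joined end-to-end with matched
#'   tangents (no closed-form ground truth).
#'
#' @param family One of `"line"`, `"arc"`, `"helix"`, `"composite"`.
#' @param a Radius of the arc or helix (mm). Must be positive for those
#'   families.
#' @param b Helix pitch parameter: rise in mm per radian of turn.
#' @param turns Number of full helix turns.
#' @param angle Arc angle in radians.
#' @param length Length of the straight segment (mm, `family = "line"`).
#' @param n_points Number of sampled points (>= 10), uniform in parameter.
#' @param noise_sd Standard deviation of isotropic Gaussian noise added to
#'   every coordinate (mm); 0 for a noiseless curve.
#' @param seed Integer seed used when `noise_sd > 0`; required then so that
#'   curves are reproducible.
#'
#' @return A tibble of class `vt_curve` with columns `x`, `y`, `z` (mm), one
#'   point per row, ordered along the curve. Attributes: `is_closed` (always
#'   `FALSE`), `ground_truth` (list with `kappa`, `tau`, `dm`, `L`, `l`, or
#'   `NULL` for composite), and `curve_spec` (the generating parameters).
#' @examples
#' helix <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200)
#' attr(helix, "ground_truth")$kappa # 3 / 25
#' @export
make_curve <- function(family = c("line", "arc", "helix", "composite"),
                       a = 3, b = 1, turns = 1, angle = pi, length = 10,
                       n_points = 100, noise_sd = 0, seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(n_points) || n_points < 10) {
    stop("`n_points` must be at least 10.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  if (family %in% c("arc", "helix") && a <= 0) {
    stop("`a` must be positive for arc and helix curves.", call. = FALSE)
  }
  n_points <- as.integer(n_points)

  pts_gt <- switch(family,
    line = {
      t <- seq(0, 1, length.out = n_points)
      list(
        pts = cbind(x = rep(0, n_points), y = rep(0, n_points), z = length * t),
        gt = list(kappa = 0, tau = 0, dm = 1, L = length, l = length)
      )
    },
    arc = {
      t <- seq(0, angle, length.out = n_points)
      L <- a * angle
      l <- 2 * a * sin(angle / 2)
      list(
        pts = cbind(x = a * cos(t), y = a * sin(t), z = rep(0, n_points)),
        gt = list(kappa = 1 / a, tau = 0, dm = l / L, L = L, l = l)
      )
    },
    helix = {
      t_max <- 2 * pi * turns
      t <- seq(0, t_max, length.out = n_points)
      L <- sqrt(a^2 + b^2) * t_max
      end <- c(a * cos(t_max) - a, a * sin(t_max), b * t_max)
      l <- sqrt(sum(end^2))
      list(
        pts = cbind(x = a * cos(t), y = a * sin(t), z = b * t),
        gt = list(kappa = a / (a^2 + b^2), tau = b / (a^2 + b^2),
                  dm = l / L, L = L, l = l)
      )
    },
    composite = {
      # line along +z, then a quarter-arc bending into +x, then a helix;
      # pieces share tangents at the joins so the composite is G1.
      n1 <- max(4L, n_points %/% 3L)
      n2 <- max(4L, n_points %/% 3L)
      n3 <- n_points - n1 - n2
      seg1 <- cbind(x = rep(0, n1), y = rep(0, n1),
                    z = seq(0, length, length.out = n1))
      th <- seq(0, pi / 2, length.out = n2 + 1)[-1]
      seg2 <- cbind(x = a - a * cos(th), y = rep(0, n2), z = length + a * sin(th))
      t3 <- seq(0, 2 * pi * turns, length.out = n3 + 1)[-1]
      org <- seg2[n2, ]
      seg3 <- cbind(x = org[1] + b * t3, y = org[2] + a * sin(t3),
                    z = org[3] + a * (cos(t3) - 1))
      list(pts = rbind(seg1, seg2, seg3), gt = NULL)
    }
  )

  pts <- pts_gt$pts
  if (noise_sd > 0) {
    if (is.null(seed)) stop("Supply `seed` when `noise_sd` > 0.", call. = FALSE)
    pts <- pts + withr::with_seed(
      as.integer(seed),
      matrix(stats::rnorm(3L * n_points, sd = noise_sd), ncol = 3)
    )
  }

  new_vt_curve(
    pts,
    ground_truth = pts_gt$gt,
    curve_spec = list(family = family, a = a, b = b, turns = turns,
                      angle = angle, length = length, n_points = n_points,
                      noise_sd = noise_sd, seed = seed)
  )
}

#' Construct a centerline curve from a matrix or data frame of 3D points
#'
#' Validates the ordered point set that represents a sampled vessel
#' centerline: at least 4 points, finite coordinates, distinct consecutive
#' points.
#'
#' @param points Matrix or data frame with 3 columns (x, y, z) in mm.
#' @param ground_truth Optional list of analytic values (`kappa`, `tau`,
#'   `dm`, `L`, `l`) when the generating geometry is known.
#' @param curve_spec Optional record of generating parameters.
#' @return A `vt_curve` tibble with columns `x`, `y`, `z`.
#' @export
new_vt_curve <- function(points, ground_truth = NULL, curve_spec = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("Curve points must have 3 columns.", call. = FALSE)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 4) stop("A curve needs at least 4 points.", call. = FALSE)
  if (!all(is.finite(pts))) stop("Curve coordinates must be finite.", call. = FALSE)
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(steps == 0)) {
    stop("Consecutive curve points must be distinct.", call. = FALSE)
  }
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  class(out) <- c("vt_curve", class(out))
  attr(out, "is_closed") <- FALSE
  attr(out, "ground_truth") <- ground_truth
  attr(out, "curve_spec") <- curve_spec
  out
}

curve_matrix <- function(curve) {
  m <- as.matrix(curve[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}

#' Chord lengths and total polyline length of a sampled curve
#'
#' @param curve A `vt_curve` or any data frame with `x`, `y`, `z` columns.
#' @return A list with `lengths` (per-segment chord lengths, mm), `L`
#'   (polyline path length), and `l` (endpoint straight-line distance).
#' @export
curve_chord_stats <- function(curve) {
  pts <- curve_matrix(curve)
  d <- diff(pts)
  lens <- sqrt(rowSums(d^2))
  list(lengths = lens, L = sum(lens),
       l = sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)))
}

#' @export
print.vt_curve <- function(x, ...) {
  cat(sprintf("<vt_curve> %d points", nrow(x)))
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) {
    cat(sprintf(" | ground truth: kappa=%.4g tau=%.4g DM=%.4g", gt$kappa,
                gt$tau, gt$dm))
  }
  cat("\n")
  NextMethod()
}

#' Orthographic projections of a 3D curve
#'
#' Plots the xy, xz and yz projections of a centerline as ggplot2 facets.
#'
#' @param curve A `vt_curve`.
#' @return A ggplot object.
#' @export
plot_curve <- function(curve) {
  pts <- tibble::as_tibble(curve[, c("x", "y", "z")])
  long <- dplyr::bind_rows(
    dplyr::transmute(pts, view = "xy", h = .data$x, v = .data$y),
    dplyr::transmute(pts, view = "xz", h = .data$x, v = .data$z),
    dplyr::transmute(pts, view = "yz", h = .data$y, v = .data$z)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm")
}
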