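#' Fit a 3D free-knot regression spline to centerline points
#'
#' Turns a discrete, possibly noisy, ordered 3D point set into an analytic
#' curve: a parametric B-spline fitted by least squares jointly over the
#' coefficients and the interior knot positions. Points are pre-parameterized
#' by chord length on \[0, 1\]; knots are then placed greedily at the
#' parameter of largest residual and all interior knot positions are locally
#' re-optimized (coefficients profiled out by linear least squares at every
#' candidate). The number of interior knots is chosen by the requested
#' criterion.
#'
#' Criteria:
#' * `"gcv"` (default): generalized cross-validation,
#'   `GCV(k) = mean(RSS) / (1 - p/n)^2` with `p = k + degree + 1` parameters
#'   per coordinate; knot insertion stops when GCV stops improving.
#' * `"aic"`: Gaussian AIC with `3 p` parameters.
#' * `"fixed"`: always use exactly `max_interior_knots` knots.
#'
#' @param curve A `vt_curve` or data frame with columns `x`, `y`, `z` (mm).
#' @param degree Spline degree; cubic (3) gives a C2 curve with third
#'   derivatives, the minimum needed for torsion.
#' @param max_interior_knots Upper bound on interior knots.
#' @param criterion Knot-count selection rule (see Details).
#' @return An object of class `vt_spline`: degree, interior knots in (0, 1),
#'   a `p x 3` coefficient matrix, the chord-length parameters of the input
#'   points, residual RMS, and an arc-length table used to map between the
#'   spline parameter and arc length.
#' @examples
#' helix <- make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200)
#' fit <- fit_free_knot_spline(helix)
#' glance(fit)
#' @export
fit_free_knot_spline <- function(curve, degree = 3, max_interior_knots = 30,
                                 criterion = c("gcv", "aic", "fixed")) {
  criterion <- match.arg(criterion)
  pts <- curve_matrix(curve)
  n <- nrow(pts)
  if (n < degree + 2) {
    stop("Need at least degree + 2 points to fit a spline.", call. = FALSE)
  }
  max_interior_knots <- min(max_interior_knots, n - degree - 2L)

  # fit in a canonical PCA frame: knot optimization then sees identical
  # coordinates whatever rigid motion the input arrived in, making the whole
  # fit equivariant to machine precision
  frame <- canonical_frame(pts)
  pts <- frame$coords

  # chord-length parameterization
  seg <- sqrt(rowSums(diff(pts)^2))
  t_raw <- c(0, cumsum(seg))
  tpar <- t_raw / t_raw[length(t_raw)]

  # knots closer than the local data spacing buy nothing and destabilize
  # derivatives; keep them at least ~1.5 samples apart
  min_gap <- max(1e-3, 1.5 / n)

  fit0 <- spline_lls(tpar, pts, degree, numeric(0))
  best <- list(knots = numeric(0), fit = fit0,
               score = knot_score(fit0$rss, n, degree, 0, criterion))
  cur_knots <- numeric(0)
  cur_fit <- fit0
  worse <- 0L

  while (length(cur_knots) < max_interior_knots) {
    cand <- propose_knot(tpar, pts, cur_fit, cur_knots, degree, min_gap)
    if (is.na(cand)) break
    knots_new <- sort(c(cur_knots, cand))
    opt <- optimize_knots(tpar, pts, degree, knots_new, min_gap)
    cur_fit <- opt$fit
    cur_knots <- cur_fit$interior
    score <- knot_score(cur_fit$rss, n, degree, length(cur_knots), criterion)
    if (criterion == "fixed" || score < best$score) {
      best <- list(fit = cur_fit, score = score)
      worse <- 0L
    } else {
      worse <- worse + 1L
      if (worse >= 3L) break  # patience: GCV/AIC has stopped improving
    }
    if (cur_fit$rss < 1e-20) break
  }
  if (criterion == "fixed") best <- list(fit = cur_fit, score = NA_real_)

  coef_world <- best$fit$coef %*% t(frame$rotation) +
    matrix(frame$center, nrow(best$fit$coef), 3, byrow = TRUE)
  obj <- structure(
    list(degree = degree, knots = best$fit$interior, coef = coef_world,
         t = tpar, n = n, rss = best$fit$rss,
         rms = sqrt(best$fit$rss / (3 * n)),
         criterion = criterion, score = best$score,
         fallback = best$fit$fallback),
    class = "vt_spline")
  obj$arclen <- arclength_table(obj)
  obj
}

# center + rotation taking the input points to a canonical PCA frame with
# deterministic axis signs (third-moment rule, first-point fallback) and a
# right-handed basis
canonical_frame <- function(pts) {
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  V <- svd(X, nu = 0)$v
  scale1 <- sqrt(mean(rowSums(X^2)))
  scale3 <- scale1^3
  endv <- X[nrow(X), ] - X[1, ]
  for (j in 1:2) {
    proj <- X %*% V[, j]
    # sign anchors in decreasing robustness: endpoint vector, third moment,
    # first point
    e <- sum(endv * V[, j])
    s3 <- sum(proj^3)
    flip <- if (abs(e) > 1e-6 * scale1) {
      e < 0
    } else if (abs(s3) > 1e-6 * scale3 * nrow(X)) {
      s3 < 0
    } else {
      proj[1] < 0
    }
    if (flip) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  # quantize the canonical coordinates: inputs that differ only by a rigid
  # motion then become bitwise identical, so the (tie-sensitive) knot search
  # follows exactly the same path for all of them
  list(center = ctr, rotation = V, coords = signif(X %*% V, 12))
}

# least-squares B-spline fit of all three coordinates for fixed knots;
# falls back to uniform knots if the design is rank-deficient
spline_lls <- function(tpar, pts, degree, interior) {
  kv <- c(rep(0, degree + 1), interior, rep(1, degree + 1))
  B <- splines::splineDesign(kv, tpar, ord = degree + 1)
  qrB <- qr(B)
  fallback <- FALSE
  if (qrB$rank < ncol(B)) {
    k <- length(interior)
    interior <- seq(0, 1, length.out = k + 2)[-c(1, k + 2)]
    warning("Free-knot optimizer produced a rank-deficient design; ",
            "falling back to uniform fixed knots.", call. = FALSE)
    kv <- c(rep(0, degree + 1), interior, rep(1, degree + 1))
    B <- splines::splineDesign(kv, tpar, ord = degree + 1)
    qrB <- qr(B)
    fallback <- TRUE
  }
  coef <- qr.coef(qrB, pts)
  resid <- pts - B %*% coef
  list(coef = coef, rss = sum(resid^2), interior = interior,
       fallback = fallback)
}

# candidate knot at the parameter of maximum residual norm, kept clear of
# existing knots and the boundary
propose_knot <- function(tpar, pts, fit, interior, degree, min_gap) {
  kv <- c(rep(0, degree + 1), interior, rep(1, degree + 1))
  B <- splines::splineDesign(kv, tpar, ord = degree + 1)
  rnorm2 <- signif(rowSums((pts - B %*% fit$coef)^2), 8)
  ord <- order(-rnorm2, tpar)  # quantized ties resolved by position
  for (i in ord) {
    cand <- tpar[i]
    if (min(abs(c(0, interior, 1) - cand)) > min_gap) return(cand)
  }
  # all high-residual points sit near existing knots: bisect the widest interval
  allk <- c(0, sort(interior), 1)
  w <- which.max(diff(allk))
  cand <- (allk[w] + allk[w + 1]) / 2
  if (min(abs(c(0, interior, 1) - cand)) <= min_gap) return(NA_real_)
  cand
}

# local optimization of all interior knots, coefficients profiled out;
# knots parameterized through normalized log-gaps to stay ordered
optimize_knots <- function(tpar, pts, degree, interior, min_gap) {
  k <- length(interior)
  if (k == 0) return(list(fit = spline_lls(tpar, pts, degree, interior)))
  gaps <- diff(c(0, sort(interior), 1))
  w0 <- log(pmax(gaps, min_gap / 4))
  big <- 1e8
  knots_of <- function(w) {
    g <- exp(w - max(w))
    cumsum(g)[seq_len(k)] / sum(g)
  }
  obj <- function(w) {
    kn <- knots_of(w)
    gp <- diff(c(0, kn, 1))
    # graded penalty (not a cliff) so the simplex can slide back to feasible
    shortfall <- sum(pmax(min_gap - gp, 0)) / min_gap
    if (shortfall > 0) return(big * (1 + shortfall))
    kv <- c(rep(0, degree + 1), kn, rep(1, degree + 1))
    B <- try(splines::splineDesign(kv, tpar, ord = degree + 1), silent = TRUE)
    if (inherits(B, "try-error")) return(big)
    qrB <- qr(B)
    if (qrB$rank < ncol(B)) return(big)
    sum((pts - B %*% qr.coef(qrB, pts))^2)
  }
  res <- try(stats::optim(w0, obj, method = "Nelder-Mead",
                          control = list(maxit = min(250L, 25L * (k + 1L)),
                                         reltol = 1e-10)),
             silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$value) || res$value >= big) {
    return(list(fit = spline_lls(tpar, pts, degree, sort(interior))))
  }
  list(fit = spline_lls(tpar, pts, degree, knots_of(res$par)))
}

knot_score <- function(rss, n, degree, k, criterion) {
  p <- k + degree + 1
  if (p >= n) return(Inf)
  switch(criterion,
    gcv = (rss / (3 * n)) / (1 - p / n)^2,
    aic = 3 * n * log(max(rss, 1e-300) / (3 * n)) + 2 * 3 * p,
    fixed = rss
  )
}

#' Evaluate a fitted spline curve and its derivatives
#'
#' @param object A `vt_spline`.
#' @param t Parameter values in \[0, 1\].
#' @param deriv Derivative order 0–3 (with respect to the spline parameter).
#' @param ... Unused.
#' @return A `length(t) x 3` matrix of coordinates (deriv = 0) or parameter
#'   derivatives.
#' @export
predict.vt_spline <- function(object, t, deriv = 0, ...) {
  stopifnot(deriv %in% 0:3)
  kv <- c(rep(0, object$degree + 1), object$knots, rep(1, object$degree + 1))
  t <- pmin(pmax(t, 0), 1)
  B <- splines::splineDesign(kv, t, ord = object$degree + 1,
                             derivs = rep(deriv, length(t)))
  out <- B %*% object$coef
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.vt_spline <- function(x, ...) {
  cat(sprintf("<vt_spline> degree %d, %d interior knots, %d points, residual RMS %.3g mm\n",
              x$degree, length(x$knots), x$n, x$rms))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_free_knot_spline
#' @param x,object A `vt_spline`.
#' @param ... Unused.
#' @method tidy vt_spline
#' @export
tidy.vt_spline <- function(x, ...) {
  tibble::tibble(knot = seq_along(x$knots), position = x$knots)
}

#' @rdname fit_free_knot_spline
#' @method glance vt_spline
#' @export
glance.vt_spline <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_interior_knots = length(x$knots),
                 n_points = x$n, rss = x$rss, residual_rms = x$rms,
                 criterion = x$criterion, score = x$score,
                 arc_length = x$arclen$L)
}

# dense parameter -> arc length lookup (monotone), plus total length by
# adaptive quadrature of |r'(t)|
arclength_table <- function(spline, n_grid = 2001) {
  tg <- seq(0, 1, length.out = n_grid)
  d1 <- predict(spline, tg, deriv = 1)
  speed <- sqrt(rowSums(d1^2))
  # composite trapezoid on the dense grid for the monotone map
  s <- c(0, cumsum((speed[-1] + speed[-n_grid]) / 2 * diff(tg)))
  L <- tryCatch(
    stats::integrate(function(u) {
      sqrt(rowSums(predict(spline, u, deriv = 1)^2))
    }, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value,
    error = function(e) s[n_grid])
  s <- s * (L / s[n_grid])
  list(t = tg, s = s, L = L)
}

# parameters uniform in arc length
param_at_arclength <- function(spline, s_target) {
  al <- spline$arclen
  stats::approx(al$s, al$t, xout = pmin(pmax(s_target, 0), al$L),
                ties = "ordered", rule = 2)$y
}

#' Curvature and torsion profile of a fitted spline curve
#'
#' Samples the fitted curve at `n_samples` points uniform in arc length and
#' evaluates the Frenet-Serret curvature and torsion from the first three
#' parameter derivatives:
#' `kappa = |r' x r''| / |r'|^3` and
#' `tau = ((r' x r'') . r''') / |r' x r''|^2`.
#' Both formulas are invariant under reparameterization. Torsion is reported
#' as its absolute value (`tau`), with the signed value retained
#' (`tau_signed`); at degenerate points where `|r' x r''| < 1e-8 |r'|^3`
#' (locally straight curve, undefined Frenet frame) torsion is set to 0.
#'
#' @param spline A `vt_spline` from [fit_free_knot_spline()].
#' @param n_samples Number of profile samples (>= 10), uniform in arc length.
#' @return A tibble of class `vt_profile` with columns `s` (arc length, mm),
#'   `t` (spline parameter), `kappa` (mm^-1, nonnegative), `tau` (mm^-1,
#'   nonnegative) and `tau_signed` (mm^-1).
#' @export
geometry_profile <- function(spline, n_samples = 200) {
  stopifnot(inherits(spline, "vt_spline"))
  if (n_samples < 10) stop("`n_samples` must be at least 10.", call. = FALSE)
  L <- spline$arclen$L
  s <- seq(0, L, length.out = n_samples)
  t <- param_at_arclength(spline, s)
  d1 <- predict(spline, t, deriv = 1)
  d2 <- predict(spline, t, deriv = 2)
  d3 <- predict(spline, t, deriv = 3)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  cr_norm <- sqrt(rowSums(cr^2))
  speed <- sqrt(rowSums(d1^2))
  kappa <- cr_norm / speed^3
  tau_signed <- rowSums(cr * d3) / cr_norm^2
  degenerate <- cr_norm < 1e-8 * speed^3
  tau_signed[degenerate] <- 0
  out <- tibble::tibble(s = s, t = t, kappa = kappa,
                        tau = abs(tau_signed), tau_signed = tau_signed)
  class(out) <- c("vt_profile", class(out))
  attr(out, "spline") <- spline
  out
}

#' Per-vessel tortuosity summary
#'
#' Reduces a curvature/torsion profile to the standard per-vessel tortuosity
#' metrics: mean, maximum and range (max - min) of curvature and of absolute
#' torsion, the total path length `L` (adaptive quadrature of `|r'|`), the
#' endpoint straight-line distance `l`, and the distance metric `DM = l / L`
#' (1 for a straight segment, smaller for tortuous ones). Means are
#' arc-length-weighted (trapezoid weights over `s`; with uniform arc-length
#' sampling this coincides with the plain mean up to endpoint treatment).
#'
#' @param profile A `vt_profile` from [geometry_profile()].
#' @param spline The `vt_spline` the profile came from; defaults to the one
#'   attached to the profile.
#' @return A one-row tibble with columns `mean_curvature`, `max_curvature`,
#'   `range_curvature`, `mean_torsion`, `max_torsion`, `range_torsion`
#'   (mm^-1), `DM` (dimensionless in (0, 1\]), `L` and `l` (mm).
#' @export
tortuosity_metrics <- function(profile, spline = attr(profile, "spline")) {
  stopifnot(inherits(profile, "vt_profile"), inherits(spline, "vt_spline"))
  L <- spline$arclen$L
  if (L <= 0) stop("Zero-length curve.", call. = FALSE)
  ends <- predict(spline, c(0, 1))
  l <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  wmean <- function(v) {
    s <- profile$s
    w <- c(diff(s) / 2, 0) + c(0, diff(s) / 2)
    sum(w * v) / sum(w)
  }
  tibble::tibble(
    mean_curvature = wmean(profile$kappa),
    max_curvature = max(profile$kappa),
    range_curvature = max(profile$kappa) - min(profile$kappa),
    mean_torsion = wmean(profile$tau),
    max_torsion = max(profile$tau),
    range_torsion = max(profile$tau) - min(profile$tau),
    DM = min(l / L, 1),
    L = L,
    l = l
  )
}

#' One-call tortuosity analysis of a sampled centerline
#'
#' Convenience pipeline: free-knot spline fit, arc-length-uniform geometry
#' profile, and metric summary.
#'
#' @inheritParams fit_free_knot_spline
#' @param n_samples Profile sample count.
#' @return A one-row tibble as [tortuosity_metrics()], with the fitted
#'   `vt_spline` and the `vt_profile` attached as attributes `spline` and
#'   `profile`.
#' @examples
#' make_curve("helix", a = 3, b = 4, turns = 1, n_points = 200) |>
#'   tortuosity()
#' @export
tortuosity <- function(curve, degree = 3, max_interior_knots = 30,
                       criterion = c("gcv", "aic", "fixed"), n_samples = 200) {
  fit <- fit_free_knot_spline(curve, degree = degree,
                              max_interior_knots = max_interior_knots,
                              criterion = criterion)
  prof <- geometry_profile(fit, n_samples = n_samples)
  out <- tortuosity_metrics(prof, fit)
  attr(out, "spline") <- fit
  attr(out, "profile") <- prof
  out
}

#' @rdname geometry_profile
#' @param object A `vt_profile`.
#' @param ... Unused.
#' @method autoplot vt_profile
#' @export
autoplot.vt_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("s", "kappa", "tau")],
    c("kappa", "tau"), names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(kappa = "curvature (1/mm)", tau = "torsion (1/mm)"))) +
    ggplot2::labs(x = "arc length s (mm)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
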