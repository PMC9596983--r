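# Independent oracles used across the suite. These never call the code paths
# they are checking.

# curvature/torsion at interior samples by central finite differences on the
# raw point sequence (uniform parameter assumed)
fd_frenet <- function(pts) {
  n <- nrow(pts)
  idx <- 3:(n - 2)
  d1 <- (pts[idx + 1, ] - pts[idx - 1, ]) / 2
  d2 <- pts[idx + 1, ] - 2 * pts[idx, ] + pts[idx - 1, ]
  d3 <- (pts[idx + 2, ] - 2 * pts[idx + 1, ] + 2 * pts[idx - 1, ] -
           pts[idx - 2, ]) / 2
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  crn <- sqrt(rowSums(cr^2))
  sp <- sqrt(rowSums(d1^2))
  list(kappa = crn / sp^3, tau = abs(rowSums(cr * d3)) / crn^2)
}

# AUC by exhaustive concordant-pair counting with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# two-sided Fisher p for a 2x2 table by exhaustive enumeration of all tables
# with the observed margins (hypergeometric point probabilities)
enum_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x) {
    stats::dhyper(x, c1, n - c1, r1)
  }, numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

apply_rigid <- function(curve, R, shift) {
  pts <- as.matrix(curve[, c("x", "y", "z")]) %*% t(R)
  pts <- pts + matrix(shift, nrow(pts), 3, byrow = TRUE)
  new_vt_curve(pts)
}
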