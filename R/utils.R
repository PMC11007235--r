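# Internal numeric helpers shared by the geometry and energy code.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-pi, pi]
#' @param x numeric angles in radians.
#' @return numeric wrapped angles.
#' @export
wrapAngle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  w[w <= -pi] <- pi  # boundary maps to +pi
  w
}

# rowwise cross product of m x 3 matrices
rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowDot <- function(a, b) rowSums(a * b)

rowNorm <- function(a) sqrt(rowSums(a * a))

# scatter-add rows of m (k x 3) into G (n x 3) at (possibly repeated) idx
scatterAdd <- function(G, idx, m) {
  if (length(idx) == 0L) return(G)
  agg <- rowsum(m, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  G[rows, ] <- G[rows, , drop = FALSE] + agg
  G
}

# all index pairs i < j with d_ij <= cutoff; returns list(i, j, d)
# plain O(N^2); adequate at the problem sizes this package targets
pairsWithin <- function(X, cutoff) {
  n <- nrow(X)
  if (n < 2L) return(list(i = integer(), j = integer(), d = numeric()))
  d2 <- as.matrix(stats::dist(X))^2
  keep <- upper.tri(d2) & d2 <= cutoff^2
  idx <- which(keep, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], d = sqrt(d2[keep]))
}

# Rodrigues rotation of points P (m x 3) about unit axis k through origin o
rotateAbout <- function(P, o, k, theta) {
  v <- sweep(P, 2, o)
  ct <- cos(theta); st <- sin(theta)
  kxv <- rowCross(matrix(k, nrow(P), 3, byrow = TRUE), v)
  kdv <- as.numeric(v %*% k)
  sweep(v * ct + kxv * st + outer(kdv * (1 - ct), k), 2, o, `+`)
}

# smooth positive part, beta controls sharpness; ~max(0, x)
softplus <- function(x, beta = 20) {
  # numerically stable log(1 + exp(beta x)) / beta
  ifelse(x > 30 / beta, x, log1p(exp(pmin(beta * x, 30))) / beta)
}

softplusGrad <- function(x, beta = 20) stats::plogis(beta * x)

sigmoid <- function(x) stats::plogis(x)
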