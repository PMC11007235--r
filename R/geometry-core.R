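# Differentiable geometric primitives: distances, bond angles, dihedrals and
# internal-coordinate (natural extension reference frame) placement, each with
# closed-form gradients with respect to the defining coordinates.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: the angle is measured looking along p2 -> p3, with
#' cis = 0 and trans = pi; result in (-pi, pi]. Degenerate configurations
#' (collinear p1-p2-p3 or p2-p3-p4) return NA rather than NaN so callers can
#' mask them.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates, or m x 3 matrices for a
#'   vectorised call.
#' @return numeric angle(s) in radians.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
    scalar <- TRUE
  } else scalar <- FALSE
  ans <- dihedralCore(p1, p2, p3, p4, grad = FALSE)$angle
  if (scalar) ans[[1]] else ans
}

# angle + optional gradients d(angle)/d(p1..p4), all m x 3
dihedralCore <- function(p1, p2, p3, p4, grad = TRUE, eps = 1e-8) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- rowCross(b1, b2)
  n2 <- rowCross(b2, b3)
  nb2 <- rowNorm(b2)
  m1 <- rowCross(n1, b2 / pmax(nb2, eps))
  x <- rowDot(n1, n2)
  y <- rowDot(m1, n2)
  ang <- atan2(-y, x)
  n1sq <- rowSums(n1 * n1)
  n2sq <- rowSums(n2 * n2)
  bad <- n1sq < eps^2 | n2sq < eps^2 | nb2 < eps
  ang[bad] <- NA_real_
  out <- list(angle = ang)
  if (grad) {
    # analytic dihedral derivatives (validated against central differences)
    safe1 <- pmax(n1sq, eps^2); safe2 <- pmax(n2sq, eps^2)
    g1 <- -n1 * (nb2 / safe1)
    g4 <- n2 * (nb2 / safe2)
    s1 <- rowDot(b1, b2) / pmax(nb2^2, eps^2)
    s2 <- rowDot(b3, b2) / pmax(nb2^2, eps^2)
    g2 <- -g1 * (1 + s1) + g4 * s2
    g3 <- g1 * s1 - g4 * (1 + s2)
    zero <- which(bad)
    if (length(zero)) {
      g1[zero, ] <- 0; g2[zero, ] <- 0; g3[zero, ] <- 0; g4[zero, ] <- 0
    }
    out$g1 <- g1; out$g2 <- g2; out$g3 <- g3; out$g4 <- g4
  }
  out
}

# bond angle at vertex b between a and c, in [0, pi], with gradients
angleCore <- function(a, b, c, grad = TRUE, eps = 1e-10) {
  u <- a - b; v <- c - b
  nu <- pmax(rowNorm(u), eps); nv <- pmax(rowNorm(v), eps)
  uh <- u / nu; vh <- v / nv
  ct <- pmin(pmax(rowDot(uh, vh), -1), 1)
  th <- acos(ct)
  out <- list(angle = th)
  if (grad) {
    st <- pmax(sqrt(1 - ct^2), 1e-8)
    ga <- (uh * ct - vh) / (nu * st)
    gc <- (vh * ct - uh) / (nv * st)
    out$ga <- ga; out$gc <- gc; out$gb <- -(ga + gc)
  }
  out
}

# Natural-extension-reference-frame placement.
# Places X bonded to c (bond length r), with angle(X, c, b) = theta and
# dihedral(X, c, b, a) = phi. theta, phi in radians.
nerfPlace <- function(a, b, c, r, theta, phi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) { # collinear support chain: pick any perpendicular
    n <- c(bc[2], -bc[1], 0)
    if (sum(n^2) < 1e-10) n <- c(0, bc[3], -bc[2])
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + bc * d[1] + m * d[2] + n * d[3]
}

#' Pairwise inter-atomic distances
#'
#' @param table an \linkS4class{AtomTable} (or bare N x 3 matrix).
#' @param cutoff optional distance cutoff in Angstrom; pairs beyond it are
#'   omitted from the sparse form.
#' @param sparse if TRUE return a data.frame of pairs (i, j, d); otherwise a
#'   dense symmetric matrix with zero diagonal.
#' @return matrix or data.frame of distances in Angstrom.
#' @export
pairwiseDistances <- function(table, cutoff = NULL, sparse = !is.null(cutoff)) {
  X <- if (is.matrix(table)) table else coords(table)
  if (nrow(X) == 0L) {
    if (sparse) return(data.frame(i = integer(), j = integer(), d = numeric()))
    return(matrix(0, 0, 0))
  }
  if (sparse) {
    p <- pairsWithin(X, cutoff %||% Inf)
    return(data.frame(i = p$i, j = p$j, d = p$d))
  }
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- NULL
  if (!is.null(cutoff)) D[D > cutoff] <- NA_real_
  diag(D) <- 0
  D
}
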