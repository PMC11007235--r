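# Periodic kernel-mixture density estimation for torsion angles: product
# von Mises kernels centred at (optionally subsampled) observations, with a
# circular Silverman bandwidth. Exactly normalised on the periodic domain
# and differentiable in the query angles.

# circular concentration -> kernel concentration via a Silverman-style rule:
# sigma_c = sqrt(-2 log Rbar), h = factor * sigma_c * n^(-1/(d+4)), k = 1/h^2
circularBandwidth <- function(theta, n, d, factor = 1, hMin = 0.015,
                              hMax = 1.5) {
  C <- mean(cos(theta)); S <- mean(sin(theta))
  rbar <- min(sqrt(C^2 + S^2), 1 - 1e-12)
  sigma <- sqrt(-2 * log(rbar))
  h <- factor * max(sigma, 1e-3) * n^(-1 / (d + 4))
  1 / min(max(h, hMin), hMax)^2
}

#' Fit a periodic torsion-angle density
#'
#' A mixture of product von Mises kernels, one per (subsampled) observation,
#' with per-dimension concentrations from a circular Silverman rule. The
#' fitted density integrates to 1 exactly over its periodic domain; its log
#' is floored and differentiable everywhere.
#'
#' @param samples numeric vector (1-D) or n x d matrix of angles in radians.
#' @param params parameter list (density settings: minimum samples, maximum
#'   kernel centers, bandwidth factor, floor).
#' @param seed integer seed controlling center subsampling.
#' @return a density component: list with \code{centers}, \code{kappa},
#'   \code{floor}.
#' @export
fitTorsionDensity <- function(samples, params = defaultParameters(),
                              seed = 1L) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  n <- nrow(samples); d <- ncol(samples)
  minS <- params$density$min_samples %||% 100
  if (n < minS)
    stop(sprintf("too few samples for density fit (%d < %d)", n, minS))
  samples <- wrapAngle(samples)
  maxC <- params$density$max_centers %||% 5000
  centers <- samples
  if (n > maxC) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    centers <- samples[sample.int(n, maxC), , drop = FALSE]
  }
  kappa <- vapply(seq_len(d), function(k)
    circularBandwidth(samples[, k], n, d,
                      factor = params$density$bandwidth_factor %||% 1),
    numeric(1))
  list(centers = centers, kappa = kappa,
       floor = params$density$floor %||% 1e-12)
}

# log I0(kappa), numerically stable for large kappa
logBesselI0 <- function(kappa) log(besselI(kappa, 0, expon.scaled = TRUE)) +
  kappa

#' Evaluate a fitted periodic density
#'
#' @param dens a density component from \code{\link{fitTorsionDensity}}.
#' @param q numeric vector (one point, or many points for 1-D densities) or
#'   m x d matrix of query angles in radians.
#' @param grad if TRUE also return d(log density)/d(angle).
#' @return list with \code{density}, \code{logDensity} and optionally
#'   \code{grad} (m x d).
#' @export
evalTorsionDensity <- function(dens, q, grad = FALSE) {
  d <- ncol(dens$centers)
  if (is.null(dim(q))) q <- matrix(q, ncol = d)
  m <- nrow(q); C <- nrow(dens$centers)
  logNorm <- sum(log(2 * pi) + logBesselI0(dens$kappa))
  # m x C matrix of summed kernel exponents
  E <- matrix(0, m, C)
  for (k in seq_len(d)) {
    dif <- outer(q[, k], dens$centers[, k], `-`)
    E <- E + dens$kappa[k] * cos(dif)
  }
  Emax <- apply(E, 1, max)
  W <- exp(E - Emax) # m x C, stable
  sumW <- rowSums(W)
  f <- exp(Emax - logNorm) * sumW / C
  fl <- dens$floor %||% 1e-12
  out <- list(density = f, logDensity = log(f + fl))
  if (grad) {
    G <- matrix(0, m, d)
    for (k in seq_len(d)) {
      dif <- outer(q[, k], dens$centers[, k], `-`)
      dfk <- exp(Emax - logNorm) *
        rowSums(W * (-dens$kappa[k] * sin(dif))) / C
      G[, k] <- dfk / (f + fl)
    }
    out$grad <- G
  }
  out
}

# numeric check: density integrates to ~1 on a periodic grid (quadrature)
densityQuadrature <- function(dens, nGrid = 360) {
  d <- ncol(dens$centers)
  if (d > 2) nGrid <- min(nGrid, 48)
  g <- seq(-pi, pi, length.out = nGrid + 1)[-1]
  grid <- as.matrix(expand.grid(rep(list(g), d)))
  f <- evalTorsionDensity(dens, grid)$density
  sum(f) * (2 * pi / nGrid)^d
}
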