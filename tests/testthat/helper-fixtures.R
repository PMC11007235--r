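# Shared fixtures and independent oracles for the test suite. The
# calibration bundle is expensive to fit, so it is memoised for the run.

.fgCache <- new.env(parent = emptyenv())

fgParams <- function() {
  if (is.null(.fgCache$params)) .fgCache$params <- defaultParameters()
  .fgCache$params
}

fgCalib <- function() {
  if (is.null(.fgCache$calib)) {
    refs <- buildReferenceSet(200, seed = 42, params = fgParams())
    .fgCache$calib <- fitCalibration(refs, fgParams(), seed = 1)
  }
  .fgCache$calib
}

fgHelix10 <- function() {
  if (is.null(.fgCache$helix10))
    .fgCache$helix10 <- addPolarHydrogens(
      buildPeptide("ADKELVRAML", preset = "helix", params = fgParams()),
      fgParams())
  .fgCache$helix10
}

# brute-force sort-and-interpolate percentile oracle (linear interpolation
# between order statistics, matching the documented convention)
percentileOracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# scalar double-loop screened-Coulomb oracle, reimplementing the pair
# selection rules independently of the tensorised code path
elecOracle <- function(at, params) {
  X <- at@coords
  n <- nrow(X)
  K <- debyeHuckelKappa(params$physical$ionic_strength,
                        params$physical$temperature)
  w <- params$weights$electrostatics
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (at@charge[i] == 0 || at@charge[j] == 0) next
    if (at@residueIndex[i] == at@residueIndex[j]) next
    key <- (min(i, j) - 1) * n + max(i, j)
    if (key %in% at@index$key12 || key %in% at@index$key13) next
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (d > params$electrostatics$cutoff) next
    d <- max(d, params$electrostatics$min_distance)
    total <- total + w * params$physical$coulomb_constant *
      at@charge[i] * at@charge[j] / (params$physical$dielectric * d) *
      exp(-d * K)
  }
  total
}

# scalar clash oracle over a precomputed pair/group table
clashOracle <- function(at, pairs, corr, params) {
  total <- 0
  w <- params$weights$clash
  for (k in seq_len(nrow(pairs))) {
    d <- sqrt(sum((at@coords[pairs$i[k], ] - at@coords[pairs$j[k], ])^2))
    gap <- d - (at@radius[pairs$i[k]] + at@radius[pairs$j[k]])
    tg <- corr[[pairs$group[k]]]
    if (gap <= tg)
      total <- total + w * exp(params$clash$slope * (tg - gap))
  }
  total
}

randomRigidMotion <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  shift <- stats::rnorm(3, 0, 20)
  list(axis = ax, theta = th, shift = shift)
}

applyRigidMotion <- function(s, rm) {
  X <- coords(s)
  ct <- cos(rm$theta); st <- sin(rm$theta)
  k <- rm$axis
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * K %*% K
  coords(s) <- sweep(X %*% t(R), 2, rm$shift, `+`)
  s
}

degToRad <- function(x) x * pi / 180

rotatePoints <- function(P, o, k, theta) {
  v <- sweep(P, 2, o)
  ct <- cos(theta); st <- sin(theta)
  kxv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
               k[3] * v[, 1] - k[1] * v[, 3],
               k[1] * v[, 2] - k[2] * v[, 1])
  kdv <- as.numeric(v %*% k)
  sweep(v * ct + kxv * st + outer(kdv * (1 - ct), k), 2, o, `+`)
}

# place chain B of a two-chain model so that acceptor `accB` sits at
# distance `d` from hydrogen `hA` along the donor->hydrogen direction
# (making the D-H...A angle exactly linear), then rotate chain B about the
# acceptor so the H...acceptor-antecedent angle hits `accAngleDeg`
placeHBondContact <- function(model, hA, donorA, accB, antB, d,
                              accAngleDeg) {
  a <- model@atoms
  X <- coords(model)
  rowsB <- which(a$chain == a$chain[accB])
  u <- X[hA, ] - X[donorA, ]; u <- u / sqrt(sum(u^2))
  target <- X[hA, ] + d * u
  X[rowsB, ] <- sweep(X[rowsB, , drop = FALSE], 2, target - X[accB, ], `+`)
  vH <- X[hA, ] - X[accB, ]; vH <- vH / sqrt(sum(vH^2))
  vA <- X[antB, ] - X[accB, ]; vA <- vA / sqrt(sum(vA^2))
  cur <- acos(pmin(pmax(sum(vH * vA), -1), 1))
  axis <- c(vA[2] * vH[3] - vA[3] * vH[2],
            vA[3] * vH[1] - vA[1] * vH[3],
            vA[1] * vH[2] - vA[2] * vH[1])
  na <- sqrt(sum(axis^2))
  if (na > 1e-8) {
    # rotating B's frame by (cur - target angle) about vA x vH moves the
    # antecedent into the requested geometry
    X[rowsB, ] <- rotatePoints(X[rowsB, , drop = FALSE], X[accB, ],
                               axis / na, cur - degToRad(accAngleDeg))
  }
  coords(model) <- X
  model
}
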