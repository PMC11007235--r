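# Deterministic synthetic-structure generation: ideal-geometry peptides by
# internal-coordinate forward kinematics, jittered calibration-grade
# reference sets, disulfide-bridged dimers and controlled clash pairs.

presetAngles <- function(preset) {
  switch(preset,
         helix = c(phi = -57, psi = -47, omega = 180),
         strand = c(phi = -120, psi = 120, omega = 180),
         stop("unknown backbone preset: ", preset))
}

# common rotamer defaults; beta-branched types need chi1 away from -60 to
# avoid backbone contacts in helices
defaultChi <- function(k, resname = "") {
  chi1 <- switch(resname, VAL = 175, THR = 62, -60)
  c(chi1, 180, 180, 180, 0)[seq_len(k)]
}

sequenceToResnames <- function(sequence) {
  letters1 <- strsplit(sequence, "")[[1]]
  res <- aminoAcids3[letters1]
  if (anyNA(res))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[is.na(res)]), collapse = ", "))
  unname(res)
}

#' Build an ideal-geometry peptide fixture
#'
#' Constructs a single-chain peptide from the internal-coordinate topology
#' template with the requested backbone preset (helix: phi = -57, psi = -47,
#' omega = 180 degrees; strand: phi = -120, psi = 120) or custom angle
#' vectors, and per-residue chi angles (default chi1 = -60, higher chi =
#' 180 degrees). Optional Gaussian coordinate noise (sd \code{noise}
#' Angstrom) is added after construction; the result is deterministic given
#' the seed.
#'
#' @param sequence one-letter amino-acid string.
#' @param preset \code{"helix"}, \code{"strand"} or \code{"custom"}.
#' @param angles for \code{preset = "custom"}: list with per-residue
#'   \code{phi}, \code{psi}, \code{omega} vectors in degrees.
#' @param chi optional n x 5 matrix of chi angles in degrees (NA = default).
#' @param noise per-atom root-mean-square displacement in Angstrom (>= 0);
#'   each coordinate receives Gaussian noise with sd \code{noise/sqrt(3)}.
#' @param seed integer seed for the noise.
#' @param chain chain identifier.
#' @param params parameter list.
#' @return a \linkS4class{StructureModel} (heavy atoms; add hydrogens with
#'   \code{\link{addPolarHydrogens}}).
#' @export
buildPeptide <- function(sequence, preset = "helix", angles = NULL,
                         chi = NULL, noise = 0, seed = 1L, chain = "A",
                         params = defaultParameters()) {
  stopifnot(nzchar(sequence), noise >= 0)
  resnames <- sequenceToResnames(sequence)
  n <- length(resnames)
  if (preset == "custom") {
    stopifnot(!is.null(angles))
    phi <- deg2rad(rep_len(angles$phi, n))
    psi <- deg2rad(rep_len(angles$psi, n))
    omega <- deg2rad(rep_len(angles$omega %||% 180, n))
  } else {
    pa <- presetAngles(preset)
    phi <- rep(deg2rad(pa["phi"]), n)
    psi <- rep(deg2rad(pa["psi"]), n)
    omega <- rep(deg2rad(pa["omega"]), n)
  }
  chiM <- matrix(NA_real_, n, 5)
  for (b in seq_len(n)) {
    k <- nChiSlots(resnames[b], params)
    if (k > 0) chiM[b, seq_len(k)] <- deg2rad(defaultChi(k, resnames[b]))
  }
  if (!is.null(chi)) {
    given <- deg2rad(chi)
    chiM[!is.na(given)] <- given[!is.na(given)]
  }
  atoms <- buildChainCoords(resnames, list(phi = phi, psi = psi,
                                           omega = omega, chi = chiM),
                            params, chain = chain)
  if (noise > 0) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    sdc <- noise / sqrt(3)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, sdc)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, sdc)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, sdc)
  }
  newStructureModel(atoms, provenance = sprintf(
    "synthetic %s peptide (n = %d, noise = %g, seed = %d)", preset, n,
    noise, seed))
}

# jittered single-chain peptide used by the reference-set generator;
# assumes RNG state is already set by the caller
jitteredPeptide <- function(resnames, preset, params, chain = "A",
                            bbJitterDeg = 8, chiJitterDeg = 12) {
  n <- length(resnames)
  pa <- presetAngles(preset)
  phi <- wrapAngle(deg2rad(pa["phi"] + stats::rnorm(n, 0, bbJitterDeg)))
  psi <- wrapAngle(deg2rad(pa["psi"] + stats::rnorm(n, 0, bbJitterDeg)))
  omega <- wrapAngle(deg2rad(pa["omega"] + stats::rnorm(n, 0, bbJitterDeg)))
  chiM <- matrix(NA_real_, n, 5)
  for (b in seq_len(n)) {
    k <- nChiSlots(resnames[b], params)
    if (k > 0)
      chiM[b, seq_len(k)] <- wrapAngle(deg2rad(
        defaultChi(k, resnames[b]) + stats::rnorm(k, 0, chiJitterDeg)))
  }
  atoms <- buildChainCoords(resnames, list(phi = phi, psi = psi,
                                           omega = omega, chi = chiM),
                            params, chain = chain,
                            geomNoise = list(angleSD = 1.5, bondSD = 0.01))
  newStructureModel(atoms, provenance = "synthetic reference peptide")
}

# two-chain construct with one disulfide bridge between central cysteines
buildDisulfideDimer <- function(params, seqA = "AACAA", preset = "strand") {
  a <- jitteredPeptide(sequenceToResnames(seqA), preset, params, chain = "A")
  b <- jitteredPeptide(sequenceToResnames(seqA), preset, params, chain = "B")
  atomsA <- a@atoms; atomsB <- b@atoms
  iSGA <- which(atomsA$atom == "SG")[1]
  iCBA <- which(atomsA$atom == "CB" & atomsA$resname == "CYS")[1]
  iSGB <- which(atomsB$atom == "SG")[1]
  iCBB <- which(atomsB$atom == "CB" & atomsB$resname == "CYS")[1]
  XA <- as.matrix(atomsA[, c("x", "y", "z")])
  XB <- as.matrix(atomsB[, c("x", "y", "z")])
  u <- XA[iSGA, ] - XA[iCBA, ]; u <- u / sqrt(sum(u^2))
  v <- XB[iSGB, ] - XB[iCBB, ]; v <- v / sqrt(sum(v^2))
  # rotate chain B so its SG-CB direction opposes u, then set the S-S bond
  axis <- c(v[2] * (-u[3]) - v[3] * (-u[2]),
            v[3] * (-u[1]) - v[1] * (-u[3]),
            v[1] * (-u[2]) - v[2] * (-u[1]))
  na <- sqrt(sum(axis^2))
  cosang <- sum(v * -u)
  if (na > 1e-8) {
    axis <- axis / na
    ang <- atan2(na, cosang)
    XB <- rotateAbout(XB, XB[iSGB, ], axis, ang)
  } else if (cosang < 0) {
    perp <- c(-v[2], v[1], 0)
    if (sum(perp^2) < 1e-8) perp <- c(0, -v[3], v[2])
    XB <- rotateAbout(XB, XB[iSGB, ], perp / sqrt(sum(perp^2)), pi)
  }
  dSS <- 2.05 + stats::rnorm(1, 0, 0.06)
  shift <- (XA[iSGA, ] + dSS * u) - XB[iSGB, ]
  XB <- sweep(XB, 2, shift, `+`)
  atomsB$x <- XB[, 1]; atomsB$y <- XB[, 2]; atomsB$z <- XB[, 3]
  newStructureModel(rbind(atomsA, atomsB),
                    provenance = "synthetic disulfide dimer")
}

# two-chain construct packed to a target minimum contact gap, emulating
# tertiary/quaternary packing so the contact groups see realistic tight
# (but observed) gaps; assumes RNG state set by the caller
buildPackedDimer <- function(params, lengthRange = c(12, 20)) {
  len <- sample(seq(lengthRange[1], lengthRange[2]), 2, replace = TRUE)
  kinds <- sample(c("helix", "strand"), 2, replace = TRUE)
  a <- jitteredPeptide(sample(unname(aminoAcids3), len[1], replace = TRUE),
                       kinds[1], params, chain = "A")
  b <- jitteredPeptide(sample(unname(aminoAcids3), len[2], replace = TRUE),
                       kinds[2], params, chain = "B")
  atomsA <- a@atoms; atomsB <- b@atoms
  XA <- as.matrix(atomsA[, c("x", "y", "z")])
  XB <- as.matrix(atomsB[, c("x", "y", "z")])
  # random orientation of chain B
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  XB <- rotateAbout(XB, colMeans(XB), ax, stats::runif(1, 0, 2 * pi))
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  radTab <- unlist(params$radii)
  rA <- unname(radTab[elementFromName(atomsA$atom)])
  rB <- unname(radTab[elementFromName(atomsB$atom)])
  target <- stats::rnorm(1, -0.25, 0.1)
  cA <- colMeans(XA)
  minGapAt <- function(L) {
    XBL <- sweep(XB, 2, cA + L * u - colMeans(XB), `+`)
    d2 <- outer(rowSums(XA^2), rowSums(XBL^2), `+`) - 2 * XA %*% t(XBL)
    min(sqrt(pmax(d2, 0)) - outer(rA, rB, `+`))
  }
  lo <- 0; hi <- 80
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (minGapAt(mid) < target) lo <- mid else hi <- mid
  }
  XB <- sweep(XB, 2, cA + hi * u - colMeans(XB), `+`)
  atomsB$x <- XB[, 1]; atomsB$y <- XB[, 2]; atomsB$z <- XB[, 3]
  newStructureModel(rbind(atomsA, atomsB),
                    provenance = "synthetic packed dimer")
}

#' Build a calibration-grade synthetic reference set
#'
#' Generates \code{n} structures whose torsion angles are drawn from
#' wrapped-normal jitter (sd 8 degrees backbone, 12 degrees chi) around the
#' preset values, so fitted densities have known ground-truth modes.
#' Sequences are uniform over the 20 standard amino acids; a configurable
#' fraction of the set consists of two-chain disulfide-bridged constructs so
#' the disulfide clash group is populated. Deterministic given the seed.
#'
#' @param n number of structures (>= 1).
#' @param lengthRange integer range of chain lengths.
#' @param mix named fractions for presets \code{helix}, \code{strand},
#'   \code{ss_dimer} (disulfide-bridged two-chain constructs) and
#'   \code{packed_dimer} (tightly packed two-chain constructs emulating
#'   tertiary contacts); normalised internally.
#' @param seed integer seed.
#' @param params parameter list.
#' @return list of \linkS4class{StructureModel}.
#' @export
buildReferenceSet <- function(n, lengthRange = c(16, 28),
                              mix = c(helix = 0.25, strand = 0.15,
                                      ss_dimer = 0.35, packed_dimer = 0.25),
                              seed = 1L, params = defaultParameters()) {
  stopifnot(n >= 1)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  mix <- mix / sum(mix)
  kinds <- sample(names(mix), n, replace = TRUE, prob = mix)
  lapply(kinds, function(kind) {
    if (kind == "ss_dimer") return(buildDisulfideDimer(params))
    if (kind == "packed_dimer") return(buildPackedDimer(params))
    len <- sample(seq(lengthRange[1], lengthRange[2]), 1)
    resnames <- sample(unname(aminoAcids3), len, replace = TRUE)
    jitteredPeptide(resnames, kind, params)
  })
}

#' Build a controlled two-residue clash fixture
#'
#' Two glycine residues on separate chains whose carbonyl oxygens face each
#' other at distance R_i + R_j + t_g + gap, where t_g is the fitted
#' correction of the \code{"other"} contact group: at \code{gap = 0} the
#' O-O pair sits exactly on the clash threshold (penalty w), positive gaps
#' are penalty-free, and each further -0.1 Angstrom multiplies the penalty
#' by e. Glycine has no intra-residue contact pairs, so the O-O contact is
#' the only clash candidate.
#'
#' @param gap offset from the group threshold, Angstrom.
#' @param calib a \linkS4class{Calibration} supplying t_g and radii.
#' @return a \linkS4class{StructureModel}.
#' @export
buildClashPair <- function(gap, calib) {
  params <- calib@params
  a <- buildPeptide("G", preset = "custom",
                    angles = list(phi = -57, psi = -47), chain = "A",
                    params = params)
  atomsA <- a@atoms
  XA <- as.matrix(atomsA[, c("x", "y", "z")])
  iO <- which(atomsA$atom == "O"); iC <- which(atomsA$atom == "C")
  u <- XA[iO, ] - XA[iC, ]; u <- u / sqrt(sum(u^2))
  rO <- unlist(params$radii)[["O"]]
  tg <- calib@clash@correction[["other"]]
  dstar <- 2 * rO + tg + gap
  # chain B is chain A rotated half a turn about a perpendicular axis
  # through the midpoint of the intended O-O contact: the oxygens (the
  # extremal atoms along u) face each other at exactly dstar
  q <- XA[iO, ] + (dstar / 2) * u
  w <- c(-u[2], u[1], 0)
  if (sum(w^2) < 1e-8) w <- c(0, -u[3], u[2])
  w <- w / sqrt(sum(w^2))
  XB <- rotateAbout(XA, q, w, pi)
  atomsB <- atomsA
  atomsB$chain <- "B"
  atomsB$x <- XB[, 1]; atomsB$y <- XB[, 2]; atomsB$z <- XB[, 3]
  newStructureModel(rbind(atomsA, atomsB),
                    provenance = sprintf("synthetic clash pair (gap = %g)",
                                         gap))
}
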