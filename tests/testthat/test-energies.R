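# The eleven energy classes: closed-form cases, scalar-loop oracles, sign
# and gating semantics, aggregation.

test_that("electrostatics matches the closed-form Coulomb case", {
  p <- fgParams()
  # q = +1 / -1 at 5 A, eps 80, I = 0: E = 332 * (-1) / (80 * 5)
  atoms <- data.frame(chain = c("A", "B"), resno = c(1, 1), icode = "",
                      resname = c("LYS", "LYS"), atom = c("NZ", "NZ"),
                      element = "N", x = c(0, 5), y = 0, z = 0, occ = 1,
                      altloc = "", stringsAsFactors = FALSE)
  m <- new("StructureModel", atoms = atoms, provenance = NA_character_)
  p0 <- p
  p0$physical$ionic_strength <- 0
  at <- assignAtomAnnotations(m, p0)
  at@charge <- c(1, -1)
  e <- electrostaticsEnergy(at, p0)
  expect_equal(sum(e$pairs$e), 332 * (-1) / (80 * 5), tolerance = 1e-10)
  # screening strictly reduces the magnitude
  pI <- p0; pI$physical$ionic_strength <- 0.15
  eI <- electrostaticsEnergy(at, pI)
  expect_lt(abs(sum(eI$pairs$e)), abs(sum(e$pairs$e)))
  # a zero charge silences every pair it is part of
  at@charge <- c(0, -1)
  expect_equal(nrow(electrostaticsEnergy(at, p0)$pairs), 0)
})

test_that("tensorised electrostatics equals the scalar double-loop oracle", {
  p <- fgParams()
  s <- addPolarHydrogens(buildPeptide("DKERDKER", preset = "strand",
                                      params = p), p)
  at <- assignAtomAnnotations(s, p)
  e <- electrostaticsEnergy(at, p)
  expect_equal(sum(e$pairs$e), elecOracle(at, p), tolerance = 1e-10)
  expect_equal(sum(e$residue), sum(e$pairs$e), tolerance = 1e-10)
  # and with zero ionic strength (K = 0, unscreened)
  p0 <- p; p0$physical$ionic_strength <- 0
  e0 <- electrostaticsEnergy(at, p0)
  expect_equal(sum(e0$pairs$e), elecOracle(at, p0), tolerance = 1e-10)
  expect_gt(abs(sum(e0$pairs$e)), abs(sum(e$pairs$e)))
})

test_that("hydrogen bonds hit -w at ideal geometry and fade when bent", {
  p <- fgParams()
  s <- buildPeptide("AAG", params = p)
  a2 <- s@atoms; a2$chain <- "B"; a2$x <- a2$x + 30
  two <- new("StructureModel",
             atoms = rbind(s@atoms, a2), provenance = NA_character_)
  two <- addPolarHydrogens(two, p)
  at0 <- assignAtomAnnotations(two, p)
  # donor: backbone H of residue 2 chain A; acceptor: O of residue 1 B
  iH <- which(at0@atomName == "H" & at0@chainIndex == 1)[1]
  iD <- at0@donorHeavy[iH]
  iA <- which(at0@atomName == "O" & at0@chainIndex == 2)[1]
  iAA <- at0@acceptorAntecedent[iA]
  ideal <- placeHBondContact(two, iH, iD, iA, iAA, 1.9, 120)
  atI <- assignAtomAnnotations(ideal, p)
  hb <- hydrogenBondEnergy(atI, p)
  best <- min(hb$pairs$e)
  # the soft acceptor assignment leaves a (temperature-sized) residual
  expect_equal(best, -p$weights$hbond, tolerance = 1e-3)
  # bend the D-H...A angle to 90 degrees: |E| < 0.25 w
  X <- coords(ideal)
  vDH <- X[iH, ] - X[iD, ]; vDH <- vDH / sqrt(sum(vDH^2))
  perp <- c(-vDH[2], vDH[1], 0)
  if (sum(perp^2) < 1e-8) perp <- c(0, -vDH[3], vDH[2])
  perp <- perp / sqrt(sum(perp^2))
  rowsB <- which(ideal@atoms$chain == "B")
  shift <- (X[iH, ] + 1.9 * perp) - X[iA, ]
  X[rowsB, ] <- sweep(X[rowsB, , drop = FALSE], 2, shift, `+`)
  bent <- ideal; coords(bent) <- X
  atB <- assignAtomAnnotations(bent, p)
  hbB <- hydrogenBondEnergy(atB, p)
  expect_lt(abs(min(c(hbB$pairs$e, 0))), 0.25 * p$weights$hbond)
  # no polar hydrogens -> zero term
  noH <- assignAtomAnnotations(buildPeptide("GGG", params = p), p)
  expect_equal(sum(hydrogenBondEnergy(noH, p)$residue), 0)
})

test_that("disulfide energy is minimal at ideal bridge geometry", {
  p <- fgParams()
  mk <- function(d, chiDeg) {
    # hand-built CYS pair: CA-CB-SG / SG-CB-CA with controlled S-S bond
    ca1 <- c(0, 0, 0); cb1 <- c(1.53, 0, 0)
    sg1 <- foldgrad:::nerfPlace(c(0, 1, 0), ca1, cb1, 1.808,
                                degToRad(113.8), degToRad(60))
    sg2 <- foldgrad:::nerfPlace(ca1, cb1, sg1, d, degToRad(103), pi)
    cb2 <- foldgrad:::nerfPlace(cb1, sg1, sg2, 1.808, degToRad(103),
                                degToRad(chiDeg))
    ca2 <- foldgrad:::nerfPlace(sg1, sg2, cb2, 1.53, degToRad(113.8),
                                degToRad(170))
    atomsA <- data.frame(
      chain = "A", resno = 1, icode = "", resname = "CYS",
      atom = c("CA", "CB", "SG"), element = c("C", "C", "S"),
      x = c(ca1[1], cb1[1], sg1[1]), y = c(ca1[2], cb1[2], sg1[2]),
      z = c(ca1[3], cb1[3], sg1[3]), occ = 1, altloc = "",
      stringsAsFactors = FALSE)
    atomsB <- data.frame(
      chain = "B", resno = 1, icode = "", resname = "CYS",
      atom = c("SG", "CB", "CA"), element = c("S", "C", "C"),
      x = c(sg2[1], cb2[1], ca2[1]), y = c(sg2[2], cb2[2], ca2[2]),
      z = c(sg2[3], cb2[3], ca2[3]), occ = 1, altloc = "",
      stringsAsFactors = FALSE)
    new("StructureModel", atoms = rbind(atomsA, atomsB),
        provenance = NA_character_)
  }
  at <- assignAtomAnnotations(mk(2.05, 90), p)
  e <- disulfideEnergy(at, p)
  expect_equal(sum(e$pairs$e), -p$weights$disulfide, tolerance = 1e-6)
  # stretched bond: strictly above the minimum
  at2 <- assignAtomAnnotations(mk(2.4, 90), p)
  e2 <- disulfideEnergy(at2, p)
  expect_gt(sum(e2$pairs$e), -p$weights$disulfide)
  expect_lt(sum(e2$pairs$e), 0)
  # no cysteines -> zero
  at3 <- assignAtomAnnotations(buildPeptide("AGA", params = fgParams()),
                               fgParams())
  expect_equal(nrow(disulfideEnergy(at3, p)$pairs), 0)
})

test_that("solvation scales linearly with residue exposure", {
  p <- fgParams()
  s <- addPolarHydrogens(buildPeptide("LKLKLK", preset = "helix",
                                      params = p), p)
  at <- assignAtomAnnotations(s, p)
  ex <- solventExposure(at, p)
  sol <- solvationEnergy(at, p)
  rt <- p$tables$residues
  cP <- rt$c_polar[match(at@residues$resname, rt$res)]
  cH <- rt$c_hydrophobic[match(at@residues$resname, rt$res)]
  expect_equal(sol$polar, cP * ex$residue, tolerance = 1e-9)
  expect_equal(sol$hydrophobic, cH * ex$residue, tolerance = 1e-9)
  # hydrophobic leucines cost more when solvent-exposed than when packed
  set.seed(2)
  iso <- addPolarHydrogens(buildPeptide("LLLLLLLL", preset = "strand",
                                        params = p), p)
  packA <- foldgrad:::buildPackedDimer(p)
  atI <- assignAtomAnnotations(iso, p)
  hI <- sum(solvationEnergy(atI, p)$hydrophobic) /
    nrow(atI@residues)
  atP <- assignAtomAnnotations(addPolarHydrogens(packA, p), p)
  exP <- solventExposure(atP, p)
  expect_gt(mean(solventExposure(atI, p)$residue),
            mean(exP$residue))
})

test_that("vdW burial term saturates and matches a scalar loop", {
  p <- fgParams()
  # a fully exposed lone residue realises no vdW stabilisation
  at1 <- assignAtomAnnotations(buildPeptide("L", params = p), p)
  expect_equal(sum(vdwEnergy(at1, p)), 0, tolerance = 1e-9)
  s <- addPolarHydrogens(buildPeptide("LVIMLVIM", preset = "helix",
                                      params = p), p)
  at <- assignAtomAnnotations(s, p)
  v <- vdwEnergy(at, p)
  ex <- solventExposure(at, p)
  rt <- p$tables$residues
  oracle <- numeric(nrow(at@residues))
  for (b in seq_len(nrow(at@residues))) {
    rows <- which(at@residueIndex == b & at@element != "H")
    cv <- rt$c_vdw[rt$res == at@residues$resname[b]]
    acc <- 0
    for (i in rows) acc <- acc + (1 - ex$atom[i]) / length(rows)
    oracle[b] <- cv * acc
  }
  expect_equal(v, oracle, tolerance = 1e-10)
  expect_true(all(v <= 1e-12))         # coefficients are stabilising
})

test_that("clash penalty obeys threshold, slope and gating", {
  calib <- fgCalib()
  p <- fgParams()
  atThr <- assignAtomAnnotations(buildClashPair(0, calib), p)
  eThr <- sum(clashEnergy(atThr, calib@clash, p))
  expect_equal(eThr, p$weights$clash, tolerance = 1e-9)
  at01 <- assignAtomAnnotations(buildClashPair(-0.1, calib), p)
  e01 <- sum(clashEnergy(at01, calib@clash, p))
  expect_equal(e01 / eThr, exp(1), tolerance = 1e-6)
  atFar <- assignAtomAnnotations(buildClashPair(2.5, calib), p)
  expect_equal(sum(clashEnergy(atFar, calib@clash, p)), 0)
  # tensorised result equals the scalar loop oracle on the helix
  s <- fgHelix10()
  at <- assignAtomAnnotations(s, p)
  cp <- foldgrad:::clashPairs(at, at@coords, p)
  expect_equal(sum(clashEnergy(at, calib@clash, p)),
               clashOracle(at, cp, calib@clash@correction, p),
               tolerance = 1e-10)
})

test_that("backbone entropy favours the fitted torsion modes", {
  calib <- fgCalib()
  p <- fgParams()
  dens <- calib@densities
  # omega near pi sits at the density mode: lower -log than a bent omega
  lpTrans <- -evalTorsionDensity(dens@omega, pi)$logDensity
  lpBent <- -evalTorsionDensity(dens@omega, 2.0)$logDensity
  expect_lt(lpTrans, lpBent)
  # a single-kernel density is lowest at its own center
  d1 <- list(centers = matrix(c(-1, -0.8), 1, 2), kappa = c(20, 20),
             floor = 1e-12)
  atC <- -evalTorsionDensity(d1, matrix(c(-1, -0.8), 1))$logDensity
  away <- -evalTorsionDensity(d1, matrix(c(-1 + pi / 2, -0.8), 1))$logDensity
  expect_lt(atC, away)
  # a residue with masked phi/psi but a valid omega contributes only the
  # omega component (drop the C atom of residue 2 to mask its phi/psi)
  s <- buildPeptide("AAAA", preset = "helix", params = fgParams())
  a <- s@atoms[!(s@atoms$resno == 2 & s@atoms$atom == "C"), ]
  sMasked <- new("StructureModel", atoms = a, provenance = NA_character_)
  atM <- assignAtomAnnotations(sMasked, p)
  be <- backboneEntropy(atM, dens, p)
  pOm <- p
  pOm$weights$entropy_backbone_phipsi <- 0
  beOm <- backboneEntropy(atM, dens, pOm)
  expect_equal(be[2], beOm[2], tolerance = 1e-9)
  # chain-initial residue has neither component defined
  expect_equal(be[1], 0)
})

test_that("side-chain entropy pays in full when interactions lock it", {
  p <- fgParams()
  # glycine and alanine carry no cost anywhere
  atGA <- assignAtomAnnotations(addPolarHydrogens(
    buildPeptide("GAGA", params = p), p), p)
  expect_equal(sum(sidechainEntropy(atGA, p)$energy), 0)
  # an isolated, fully exposed lysine pays almost nothing
  atK <- assignAtomAnnotations(addPolarHydrogens(
    buildPeptide("K", params = p), p), p)
  seK <- sidechainEntropy(atK, p)
  expect_lt(seK$energy[1], 0.1)
  # the same lysine whose NZ hydrogen donates a salt-bridge hydrogen bond
  # pays (close to) the full cost
  sK <- addPolarHydrogens(buildPeptide("K", params = p), p)
  aD <- buildPeptide("D", chain = "B", params = p)
  aD@atoms$x <- aD@atoms$x + 30
  both <- new("StructureModel",
              atoms = rbind(sK@atoms, aD@atoms),
              provenance = NA_character_)
  at0 <- assignAtomAnnotations(both, p)
  iH <- which(at0@atomName == "HZ1")
  iD <- at0@donorHeavy[iH]
  iA <- which(at0@atomName == "OD1")
  iAA <- at0@acceptorAntecedent[iA]
  bridged <- placeHBondContact(both, iH, iD, iA, iAA, 1.9, 120)
  atBr <- assignAtomAnnotations(bridged, p)
  seBr <- sidechainEntropy(atBr, p)
  sLys <- p$tables$residues$s_entropy[p$tables$residues$res == "LYS"]
  expect_gt(seBr$gate[1], 0.8)
  expect_gt(seBr$energy[1], 0.8 * sLys)
})

test_that("violation terms are non-negative with correct minima", {
  calib <- fgCalib()
  p <- fgParams()
  s <- fgHelix10()
  at <- assignAtomAnnotations(s, p)
  pv <- peptideViolation(at, calib@densities, p)
  sv <- sidechainViolation(at, calib@densities, p)
  expect_true(all(pv >= 0))
  expect_true(all(sv >= 0))
  # on the ideal fixture the peptide geometry sits at the fitted means
  expect_lt(sum(pv), 0.05)
  # displacing one estimator by exactly 1 sigma costs w/2
  densShift <- calib@densities
  gp <- densShift@peptide
  pg <- peptideGeometry(s, p)
  gp$mean[gp$name == "dist_N_Cp"] <- pg$dist_N_Cp[1] -
    gp$sd[gp$name == "dist_N_Cp"]
  gp$mean[gp$name == "angle_CA_N_Cp"] <- pg$angle_CA_N_Cp[1]
  gp$mean[gp$name == "angle_CAp_Cp_N"] <- pg$angle_CAp_Cp_N[1]
  densShift@peptide <- gp
  pv2 <- peptideViolation(at, densShift, p)
  expect_equal(pv2[2], p$weights$peptide_violation * 0.5,
               tolerance = 1e-4)
  # chain break contributes zero
  a2 <- s@atoms
  mid <- a2$resno > 5
  a2$x[mid] <- a2$x[mid] + 50
  sBroken <- new("StructureModel", atoms = a2, provenance = NA_character_)
  atB <- assignAtomAnnotations(sBroken, p)
  pvB <- peptideViolation(atB, calib@densities, p)
  expect_equal(pvB[6], 0)
  # residues without chi (Gly/Ala) contribute zero side-chain violation
  atGA <- assignAtomAnnotations(buildPeptide("GAGA", params = p), p)
  expect_equal(sum(sidechainViolation(atGA, calib@densities, p)), 0)
  # the density itself is periodic: +2 pi changes nothing
  d <- calib@densities@chi[["SER"]]
  v1 <- evalTorsionDensity(d, matrix(0.7, 1))$logDensity
  v2 <- evalTorsionDensity(d, matrix(0.7 + 2 * pi, 1))$logDensity
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("total energy aggregates the terms into one consistent value", {
  calib <- fgCalib()
  s <- fgHelix10()
  bd <- totalEnergy(s, calib)
  expect_s4_class(bd, "EnergyBreakdown")
  expect_equal(bd@total, sum(bd@energies),
               tolerance = 1e-6 * max(1, abs(bd@total)))
  expect_equal(nrow(bd@energies), 11)
  expect_true(all(is.finite(bd@energies)))
  # empty structure: all terms zero
  empty <- new("StructureModel", atoms = foldgrad:::emptyAtoms(),
               provenance = NA_character_)
  bd0 <- totalEnergy(empty, calib)
  expect_equal(bd0@total, 0)
  # two copies 100 A apart: exactly twice the monomer energy
  a <- s@atoms
  a2 <- a; a2$chain <- "B"; a2$x <- a2$x + 100
  dimer <- new("StructureModel", atoms = rbind(a, a2),
               provenance = NA_character_)
  bd2 <- totalEnergy(dimer, calib)
  expect_equal(bd2@total, 2 * bd@total,
               tolerance = 1e-6 * max(1, abs(bd@total)))
})
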