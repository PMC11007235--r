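# Geometric primitives: dihedrals, distances, torsion extraction, exposure,
# peptide geometry and forward kinematics.

test_that("dihedral angle follows the standard sign convention", {
  # planar cis arrangement -> 0, trans -> pi
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), 0, tolerance = 1e-12)
  expect_equal(abs(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                                 c(3, -1, 0))), pi, tolerance = 1e-12)
  set.seed(11)
  for (k in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4, 3) + rep(1:4, 3)
    ang <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
    # order reversal leaves a torsion angle unchanged
    expect_equal(dihedralAngle(p[4, ], p[3, ], p[2, ], p[1, ]), ang,
                 tolerance = 1e-12)
    # mirror reflection negates it
    q <- p; q[, 3] <- -q[, 3]
    expect_equal(dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]), -ang,
                 tolerance = 1e-9)
  }
})

test_that("dihedral matches an explicit rotation-matrix construction", {
  # build a chain where the fourth point is rotated about the bond axis by
  # a known angle from the cis reference, for a tetrahedral-like geometry
  set.seed(3)
  for (target in c(-2.5, -pi / 3, 0.4, pi / 3, 3)) {
    a <- c(-1, 1, 0); b <- c(0, 0, 0); c <- c(1.5, 0, 0)
    d0 <- c + c(0.5, 1.2, 0)            # cis position relative to a
    axis <- (c - b) / sqrt(sum((c - b)^2))
    v <- d0 - c
    ct <- cos(target); st <- sin(target)
    kxv <- c(axis[2] * v[3] - axis[3] * v[2],
             axis[3] * v[1] - axis[1] * v[3],
             axis[1] * v[2] - axis[2] * v[1])
    d <- c + v * ct + kxv * st + axis * sum(axis * v) * (1 - ct)
    got <- dihedralAngle(a, b, c, d)
    # the rotation oracle fixes the angle up to the sign convention of the
    # rotation sense; compare magnitudes and periodic position
    expect_equal(cos(got), cos(target), tolerance = 1e-9)
    expect_equal(abs(sin(got)), abs(sin(target)), tolerance = 1e-9)
  }
})

test_that("dihedral agrees with an independent torsion implementation", {
  set.seed(5)
  for (k in 1:20) {
    p <- rnorm(12, sd = 3)
    expect_equal(dihedralAngle(p[1:3], p[4:6], p[7:9], p[10:12]),
                 bio3d::torsion.xyz(p) * pi / 180, tolerance = 1e-8)
  }
})

test_that("pairwise distances are exact and match a scalar loop", {
  X <- rbind(c(0, 0, 0), c(3, 4, 0))
  D <- pairwiseDistances(X)
  expect_equal(D[1, 2], 5)
  expect_equal(diag(D), c(0, 0))
  set.seed(7)
  X <- matrix(rnorm(150, sd = 5), 50, 3)
  D <- pairwiseDistances(X)
  expect_true(isSymmetric(D))
  for (pick in list(c(1, 2), c(10, 40), c(25, 26), c(3, 50))) {
    d <- sqrt(sum((X[pick[1], ] - X[pick[2], ])^2))
    expect_equal(D[pick[1], pick[2]], d, tolerance = 1e-10)
  }
  loop <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    loop[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  expect_equal(max(abs(D - loop)), 0, tolerance = 1e-10)
  sp <- pairwiseDistances(X, cutoff = 4)
  expect_true(all(sp$d <= 4))
})

test_that("backbone torsions recover construction angles and mask termini", {
  p <- fgParams()
  s <- buildPeptide("AAAAAAAA", preset = "helix", params = p)
  t <- backboneTorsions(s, p)
  expect_true(is.na(t@phi[1]))          # no preceding C
  expect_true(is.na(t@psi[8]))          # no following N
  expect_true(is.na(t@omega[1]))
  inner <- 2:7
  expect_equal(t@phi[inner], rep(-57 * pi / 180, 6), tolerance = 1e-6)
  expect_equal(t@psi[inner], rep(-47 * pi / 180, 6), tolerance = 1e-6)
  expect_equal(abs(t@omega[inner]), rep(pi, 6), tolerance = 1e-6)
  s1 <- buildPeptide("A", params = p)
  t1 <- backboneTorsions(s1, p)
  expect_true(all(is.na(c(t1@phi, t1@psi, t1@omega))))
})

test_that("chi torsions follow the standard per-type slot counts", {
  p <- fgParams()
  s <- buildPeptide("GAKRV", preset = "strand", params = p)
  t <- chiTorsions(s, p)
  nValid <- rowSums(!is.na(t@chi))
  expect_equal(nValid, c(0, 0, 4, 5, 1))  # Gly, Ala, Lys, Arg (max), Val
})

test_that("solvent exposure behaves as a smooth occlusion measure", {
  p <- fgParams()
  # a lone residue reads fully exposed
  at1 <- assignAtomAnnotations(buildPeptide("G", params = p), p)
  ex1 <- solventExposure(at1, p)
  expect_equal(ex1$residue, 1, tolerance = 1e-12)
  # an atom enclosed by 30 neighbours at 3.5 A reads < 0.1: one CA per
  # pseudo-residue so occlusion counts every neighbour
  th <- acos(1 - 2 * (1:30) / 31)
  ph <- sqrt(pi * 30) * th
  shell <- 3.5 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  atoms <- data.frame(chain = "A", resno = 1:31, icode = "",
                      resname = "GLY", atom = "CA", element = "C",
                      x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                      z = c(0, shell[, 3]), occ = 1, altloc = "",
                      stringsAsFactors = FALSE)
  m <- new("StructureModel", atoms = atoms, provenance = NA_character_)
  at <- assignAtomAnnotations(m, p)
  ex <- solventExposure(at, p)
  expect_lt(ex$atom[1], 0.1)
  # exposure strictly decreases as a neighbour approaches
  vals <- vapply(c(8, 6, 4.5, 3), function(d) {
    atoms2 <- atoms[1:2, ]
    atoms2[2, c("x", "y", "z")] <- c(d, 0, 0)
    m2 <- new("StructureModel", atoms = atoms2,
              provenance = NA_character_)
    solventExposure(assignAtomAnnotations(m2, p), p)$atom[1]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # the helix fixture separates buried core from exposed surface
  sh <- addPolarHydrogens(buildPeptide("ALKDELVRAMLEWIKSNQTA",
                                       preset = "helix", params = p), p)
  exh <- solventExposure(assignAtomAnnotations(sh, p), p)
  expect_lt(min(exh$atom, na.rm = TRUE), 0.2)
  expect_gt(max(exh$atom, na.rm = TRUE), 0.7)
})

test_that("peptide geometry reports per-bond observations and breaks", {
  p <- fgParams()
  s <- buildPeptide("AAAA", preset = "helix", params = p)
  pg <- peptideGeometry(s, p)
  expect_equal(nrow(pg), 3)
  expect_equal(pg$dist_N_Cp, rep(1.329, 3), tolerance = 1e-6)
  expect_false(any(pg$excluded))
  # no observation across a chain boundary
  a2 <- s@atoms; a2$chain[a2$resno > 2] <- "B"
  s2 <- new("StructureModel", atoms = a2, provenance = NA_character_)
  expect_equal(nrow(peptideGeometry(s2, p)), 2)
  # a 4 A gap flags the bond as excluded
  a3 <- s@atoms
  shift <- a3$resno > 2
  a3$x[shift] <- a3$x[shift] + 4
  s3 <- new("StructureModel", atoms = a3, provenance = NA_character_)
  pg3 <- peptideGeometry(s3, p)
  expect_true(any(pg3$excluded))
})

test_that("torsion rebuild round-trips and respects causality", {
  p <- fgParams()
  s <- buildPeptide("ADKELV", preset = "helix", params = p)
  t <- backboneTorsions(s, p)
  rb <- rebuildFromTorsions(t, p)
  expect_equal(foldgrad:::alignedRMSD(coords(s), coords(rb)), 0,
               tolerance = 1e-3)
  # perturbing phi of residue 4 leaves residues 1-3 untouched
  t2 <- t
  t2@phi[4] <- t2@phi[4] + 0.3
  rb2 <- rebuildFromTorsions(t2, p)
  n3 <- sum(residueIndex(rb) <= 3)
  expect_lt(max(abs(coords(rb)[1:n3, ] - coords(rb2)[1:n3, ])), 1e-9)
  expect_gt(max(abs(coords(rb) - coords(rb2))), 0.01)
  # rotating one omega by pi matches an explicit axis-angle rotation
  t3 <- t
  t3@omega[4] <- foldgrad::wrapAngle(t3@omega[4] + pi)
  rb3 <- rebuildFromTorsions(t3, p)
  X <- coords(rb)
  idx <- foldgrad:::modelIndexTables(rb, p)
  q <- idx$omegaIdx[4, ]
  axis <- X[q[3], ] - X[q[2], ]
  axis <- axis / sqrt(sum(axis^2))
  downstream <- which(residueIndex(rb) >= 4 &
                        seq_len(nAtoms(rb)) != q[3])
  expected <- rotatePoints(X[downstream, , drop = FALSE], X[q[3], ], axis,
                           pi)
  expect_equal(max(abs(coords(rb3)[downstream, ] - expected)), 0,
               tolerance = 1e-6)
})

test_that("geometry outputs are invariant under rigid motion", {
  p <- fgParams()
  s <- buildPeptide("ADKELV", preset = "helix", params = p)
  t0 <- backboneTorsions(s, p)
  ex0 <- solventExposure(assignAtomAnnotations(s, p), p)
  set.seed(21)
  for (k in 1:5) {
    s2 <- applyRigidMotion(s, randomRigidMotion())
    t2 <- backboneTorsions(s2, p)
    circDiff <- function(a, b) { # identical angles, allowing the +/- pi seam
      d <- abs(wrapAngle(a - b))
      max(d[!is.na(d)], 0)
    }
    expect_lt(circDiff(t2@phi, t0@phi), 1e-9)
    expect_lt(circDiff(t2@psi, t0@psi), 1e-9)
    expect_lt(circDiff(t2@chi, t0@chi), 1e-9)
    ex2 <- solventExposure(assignAtomAnnotations(s2, p), p)
    expect_equal(ex2$residue, ex0$residue, tolerance = 1e-9)
  }
})

test_that("primitive gradients match central finite differences", {
  set.seed(31)
  h <- 1e-5
  for (rep in 1:5) {
    P <- matrix(rnorm(12, sd = 2), 4, 3) + rep(c(0, 1, 2, 3), 3)
    dc <- foldgrad:::dihedralCore(P[1, , drop = FALSE], P[2, , drop = FALSE],
                                  P[3, , drop = FALSE], P[4, , drop = FALSE])
    ac <- foldgrad:::angleCore(P[1, , drop = FALSE], P[2, , drop = FALSE],
                               P[3, , drop = FALSE])
    for (w in 1:4) for (k in 1:3) {
      Pp <- P; Pp[w, k] <- Pp[w, k] + h
      Pm <- P; Pm[w, k] <- Pm[w, k] - h
      fd <- (dihedralAngle(Pp[1, ], Pp[2, ], Pp[3, ], Pp[4, ]) -
               dihedralAngle(Pm[1, ], Pm[2, ], Pm[3, ], Pm[4, ])) / (2 * h)
      expect_equal(dc[[paste0("g", w)]][1, k], fd, tolerance = 1e-5)
      if (w <= 3) {
        fdA <- (foldgrad:::angleCore(Pp[1, , drop = FALSE],
                                     Pp[2, , drop = FALSE],
                                     Pp[3, , drop = FALSE],
                                     grad = FALSE)$angle -
                  foldgrad:::angleCore(Pm[1, , drop = FALSE],
                                       Pm[2, , drop = FALSE],
                                       Pm[3, , drop = FALSE],
                                       grad = FALSE)$angle) / (2 * h)
        g <- list(ac$ga, ac$gb, ac$gc)[[w]]
        expect_equal(g[1, k], fdA, tolerance = 1e-5)
      }
    }
  }
})
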