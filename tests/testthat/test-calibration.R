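# Physical constants, clash-group corrections, torsion densities and
# peptide Gaussians.

test_that("Debye-Huckel parameter follows the physical-constant product", {
  expect_equal(debyeHuckelKappa(0), 0)
  expect_equal(debyeHuckelKappa(4 * 0.1), 2 * debyeHuckelKappa(0.1),
               tolerance = 1e-12)
  # independent scalar evaluation with CODATA constants (CGS):
  # K = sqrt(8 pi e^2 N_A I / (1000 k T)), converted to 1/Angstrom
  e <- 4.80320471e-10; NAv <- 6.02214076e23; kB <- 1.380649e-16
  oracle <- sqrt(8 * pi * e^2 * NAv * 0.15 / (1000 * kB * 298)) * 1e-8
  expect_equal(debyeHuckelKappa(0.15, 298), oracle, tolerance = 1e-12)
  # monotone increasing in I, decreasing in T
  Is <- c(0.01, 0.05, 0.1, 0.5)
  expect_true(all(diff(debyeHuckelKappa(Is, 298)) > 0))
  Ts <- c(273, 298, 310, 350)
  expect_true(all(diff(debyeHuckelKappa(0.1, Ts)) < 0))
  expect_error(debyeHuckelKappa(-0.1), "ionic strength")
  expect_error(debyeHuckelKappa(0.1, 0), "temperature")
})

test_that("clash corrections reproduce the sort-based percentile oracle", {
  calib <- fgCalib()
  # the fitted corrections use linear interpolation between order
  # statistics; re-derive one group from scratch with the oracle
  p <- fgParams()
  refs <- buildReferenceSet(12, seed = 7, params = p)
  gaps <- NULL
  for (s in refs) {
    sh <- addPolarHydrogens(s, p)
    at <- assignAtomAnnotations(sh, p)
    cp <- foldgrad:::clashPairs(at, at@coords, p)
    g <- cp$d - (at@radius[cp$i] + at@radius[cp$j])
    gaps <- rbind(gaps, data.frame(g = g, grp = cp$group))
  }
  p2 <- p; p2$clash$min_group_count <- 1
  fit <- fitClashCorrections(refs, p2)
  for (grp in unique(gaps$grp)) {
    expect_equal(fit@correction[[grp]],
                 percentileOracle(gaps$g[gaps$grp == grp], 0.10),
                 tolerance = 1e-12)
  }
  # synthetic 10-value example: -0.5, -0.4, ..., +0.4
  vals <- seq(-0.5, 0.4, by = 0.1)
  expect_equal(percentileOracle(vals, 0.10),
               unname(quantile(vals, 0.10, type = 7)), tolerance = 1e-12)
  # percentile invariant under duplication of the sample
  expect_equal(unname(quantile(c(vals, vals), 0.10, type = 7)),
               unname(quantile(vals, 0.10, type = 7)), tolerance = 1e-12)
})

test_that("degenerate reference sets are rejected with the group named", {
  p <- fgParams()
  # single tiny peptide: disulfide (and most) groups are unpopulated
  refs <- list(buildPeptide("AA", params = p))
  expect_error(fitClashCorrections(refs, p), "disulfide")
})

test_that("fitted torsion densities are normalised with planted modes", {
  p <- fgParams()
  # single sample at 0: maximal and symmetric about 0
  p1 <- p; p1$density$min_samples <- 1
  d1 <- fitTorsionDensity(0, params = p1)
  q <- seq(-pi, pi, length.out = 181)
  f <- evalTorsionDensity(d1, q)$density
  expect_equal(q[which.max(f)], 0, tolerance = 0.02)
  expect_equal(f, rev(f), tolerance = 1e-9)
  # 2-D fitted density integrates to 1 on a 360 x 360 grid
  set.seed(5)
  ang <- cbind(rnorm(500, -1, 0.3), rnorm(500, 2, 0.4))
  d2 <- fitTorsionDensity(ang, params = p)
  expect_equal(foldgrad:::densityQuadrature(d2, 360), 1, tolerance = 0.01)
  # two-component wrapped mixture: recovered modes within 5 degrees
  set.seed(9)
  comp <- sample(c(-2, 1.5), 2000, replace = TRUE)
  th <- foldgrad::wrapAngle(comp + rnorm(2000, 0, 0.25))
  dm <- fitTorsionDensity(th, params = p)
  fg <- evalTorsionDensity(dm, q)$density
  top <- q[order(fg, decreasing = TRUE)]
  m1 <- top[1]
  m2 <- top[which(abs(foldgrad::wrapAngle(top - m1)) > 1)[1]]
  got <- sort(c(m1, m2))
  expect_lt(max(abs(got - c(-2, 1.5))), 5 * pi / 180)
  # too few samples is an error
  expect_error(fitTorsionDensity(rnorm(10), params = p), "too few")
})

test_that("peptide Gaussians recover parameters and floor the sd", {
  p <- fgParams()
  obs <- data.frame(angle_CA_N_Cp = rep(2.1, 100),
                    angle_CAp_Cp_N = rep(2.0, 100),
                    dist_N_Cp = rep(1.33, 100), excluded = FALSE)
  g <- fitPeptideGaussians(obs, p)
  expect_equal(g$mean, c(2.1, 2.0, 1.33))
  expect_equal(g$sd, rep(p$peptide$sigma_floor, 3))
  set.seed(13)
  obs2 <- data.frame(angle_CA_N_Cp = rnorm(1000, 2.124, 0.02),
                     angle_CAp_Cp_N = rnorm(1000, 2.028, 0.02),
                     dist_N_Cp = rnorm(1000, 1.33, 0.01),
                     excluded = FALSE)
  g2 <- fitPeptideGaussians(obs2, p)
  expect_equal(g2$mean[3], 1.33, tolerance = 0.001)
  expect_equal(g2$sd[3], 0.01, tolerance = 0.1 * 0.01 / 0.01)
  expect_lt(abs(g2$sd[3] - 0.01) / 0.01, 0.10)
  expect_error(fitPeptideGaussians(obs[1:3, ], p), "too few")
})

test_that("calibration bundle serialises and round-trips through YAML", {
  calib <- fgCalib()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeCalibration(calib, f)
  calib2 <- readCalibration(f)
  expect_equal(calib2@clash@correction, calib@clash@correction,
               tolerance = 1e-9)
  expect_equal(calib2@clash@counts, calib@clash@counts)
  expect_equal(calib2@densities@peptide$mean, calib@densities@peptide$mean,
               tolerance = 1e-9)
  expect_equal(sort(names(calib2@densities@backbone)),
               sort(names(calib@densities@backbone)))
  d1 <- calib@densities@chi[["LYS"]]; d2 <- calib2@densities@chi[["LYS"]]
  expect_equal(d2$kappa, d1$kappa, tolerance = 1e-9)
  expect_equal(dim(d2$centers), dim(d1$centers))
  # evaluated energies agree between the two bundles
  s <- fgHelix10()
  e1 <- totalEnergy(s, calib)@total
  e2 <- totalEnergy(s, calib2)@total
  expect_equal(e2, e1, tolerance = 1e-6)
})

test_that("all fitted densities are normalised and finite on a grid", {
  calib <- fgCalib()
  dens <- calib@densities
  expect_equal(foldgrad:::densityQuadrature(dens@omega, 720), 1,
               tolerance = 0.01)
  for (rt in c("ALA", "LYS", "GLY")) {
    expect_equal(foldgrad:::densityQuadrature(dens@backbone[[rt]], 180), 1,
                 tolerance = 0.01)
  }
  q <- seq(-pi, pi, length.out = 181)
  lf <- evalTorsionDensity(dens@omega, q)$logDensity
  expect_true(all(is.finite(lf)))
})
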