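# Calibration: the screened-Coulomb Debye-Huckel parameter, clash-group
# distance corrections fitted from reference-structure contact statistics,
# torsion densities and peptide-geometry Gaussians, plus (de)serialisation
# of the whole bundle to a human-readable YAML file.

#' Debye-Huckel screening parameter
#'
#' K = sqrt(8 pi e^2 N_A I / (1000 k_B T)) evaluated in CGS units and
#' converted so that d * K is dimensionless when d is in Angstrom. K = 0 at
#' zero ionic strength (unscreened Coulomb); K scales with sqrt(I) and
#' 1/sqrt(T).
#'
#' @param I ionic strength, molar (>= 0).
#' @param T temperature, Kelvin (> 0).
#' @return K in 1/Angstrom.
#' @export
debyeHuckelKappa <- function(I, T = 298) {
  if (any(I < 0)) stop("ionic strength must be >= 0")
  if (any(T <= 0)) stop("temperature must be > 0")
  eEsu <- 4.80320471e-10   # elementary charge, esu
  NA_ <- 6.02214076e23     # Avogadro
  kB <- 1.380649e-16       # Boltzmann, erg/K
  kCm <- sqrt(8 * pi * eEsu^2 * NA_ * I / (1000 * kB * T))
  kCm * 1e-8               # cm^-1 -> Angstrom^-1
}

# geometric hydrogen-bond detection (for pair grouping and entropy gating):
# donor-H ... acceptor within dCut with a D-H...A angle above angMin
hbondGeometric <- function(at, X, dCut = 2.5, angMinDeg = 100) {
  hs <- which(at@isDonorH)
  ac <- which(at@isAcceptor)
  if (!length(hs) || !length(ac))
    return(data.frame(h = integer(), a = integer(), d = integer()))
  out <- list()
  for (h in hs) {
    dv <- sqrt(colSums((t(X[ac, , drop = FALSE]) - X[h, ])^2))
    near <- ac[dv <= dCut]
    near <- near[near != at@donorHeavy[h]]
    if (!length(near)) next
    dh <- at@donorHeavy[h]
    for (a in near) {
      th <- angleCore(X[dh, , drop = FALSE], X[h, , drop = FALSE],
                      X[a, , drop = FALSE], grad = FALSE)$angle
      if (th >= deg2rad(angMinDeg))
        out[[length(out) + 1L]] <- c(h, a, dh)
    }
  }
  if (!length(out)) return(data.frame(h = integer(), a = integer(),
                                      d = integer()))
  m <- do.call(rbind, out)
  data.frame(h = m[, 1], a = m[, 2], d = m[, 3])
}

# Collect candidate clash pairs within the 5 A radius, apply the exclusions
# (covalent except disulfide, rigid groups, same-residue backbone), and
# assign each pair to one of the six contact groups.
clashPairs <- function(at, X = at@coords, params = defaultParameters()) {
  cutoff <- params$clash$pair_cutoff %||% 5
  p <- pairsWithin(X, cutoff)
  n <- nrow(X)
  if (!length(p$i))
    return(data.frame(i = integer(), j = integer(), d = numeric(),
                      group = character()))
  keys <- pairKey(p$i, p$j, n)
  idx <- at@index
  ssKeys <- if (nrow(idx$ssPairs)) pairKey(idx$ssPairs[, 1],
                                           idx$ssPairs[, 2], n) else numeric()
  # covalent 1-2 pairs (except the disulfide bond itself) and angle-rigid
  # 1-3 pairs are part of the covalent frame, not contacts
  keep <- !(keys %in% setdiff(idx$key12, ssKeys)) & !(keys %in% idx$key13)
  # rigid geometrical units: same aromatic ring; proline Cdelta against the
  # preceding carbonyl
  rigid <- rep(FALSE, length(p$i))
  rt <- params$tables$rigid
  sameRes <- at@residueIndex[p$i] == at@residueIndex[p$j]
  for (k in seq_len(nrow(rt))) {
    atoms <- strsplit(rt$atoms[k], ",")[[1]]
    inRing <- at@resname == rt$res[k] & at@atomName %in% atoms
    rigid <- rigid | (sameRes & inRing[p$i] & inRing[p$j])
  }
  proCD <- at@resname == "PRO" & at@atomName == "CD"
  carbonyl <- at@atomName %in% c("C", "O")
  consec <- abs(at@residueIndex[p$i] - at@residueIndex[p$j]) == 1L &
    at@chainIndex[p$i] == at@chainIndex[p$j]
  rigid <- rigid | (consec & ((proCD[p$i] & carbonyl[p$j]) |
                                (proCD[p$j] & carbonyl[p$i])))
  bbPair <- sameRes & at@isBackbone[p$i] & at@isBackbone[p$j]
  keep <- keep & !rigid & !bbPair
  i <- p$i[keep]; j <- p$j[keep]; d <- p$d[keep]; keys <- keys[keep]
  sameRes <- sameRes[keep]; consec <- consec[keep]

  hb <- hbondGeometric(at, X)
  hbKeys <- numeric()
  if (nrow(hb))
    hbKeys <- unique(c(pairKey(hb$h, hb$a, n), pairKey(hb$d, hb$a, n)))
  donorHeavyFlag <- rep(FALSE, n)
  donorHeavyFlag[stats::na.omit(at@donorHeavy)] <- TRUE
  donorAtom <- at@isDonorH | donorHeavyFlag
  grp <- rep("other", length(i))
  da <- (donorAtom[i] & at@isAcceptor[j]) | (donorAtom[j] & at@isAcceptor[i])
  grp[da] <- "donor_acceptor"
  grp[consec & at@isBackbone[i] & at@isBackbone[j]] <- "consecutive_backbone"
  grp[keys %in% hbKeys] <- "hbond"
  grp[sameRes] <- "same_residue"
  grp[keys %in% ssKeys] <- "disulfide"
  data.frame(i = i, j = j, d = d, group = grp, stringsAsFactors = FALSE)
}

#' Fit clash-group distance corrections
#'
#' Collects every atom pair within 5 Angstrom across the reference set,
#' applies the exclusions (covalently bonded pairs except disulfides, rigid
#' groups such as aromatic rings and the proline Cdelta/preceding-carbonyl
#' contact, same-residue backbone pairs), assigns the remaining pairs to the
#' six contact groups, and takes the 10th percentile (linear interpolation
#' between order statistics) of the contact gap d - (R_i + R_j) per group.
#'
#' @param refs list of \linkS4class{StructureModel} reference structures
#'   (polar hydrogens are placed and annotations assigned internally).
#' @param params parameter list.
#' @return a \linkS4class{ClashGroupTable}.
#' @export
fitClashCorrections <- function(refs, params = defaultParameters()) {
  gaps <- stats::setNames(vector("list", 6), clashGroupNames)
  for (s in refs) {
    sh <- addPolarHydrogens(s, params)
    at <- assignAtomAnnotations(sh, params)
    cp <- clashPairs(at, at@coords, params)
    if (!nrow(cp)) next
    g <- cp$d - (at@radius[cp$i] + at@radius[cp$j])
    for (grp in unique(cp$group))
      gaps[[grp]] <- c(gaps[[grp]], g[cp$group == grp])
  }
  counts <- vapply(gaps, length, integer(1))
  minC <- params$clash$min_group_count %||% 50
  low <- names(counts)[counts < minC]
  if (length(low))
    stop("too few reference pairs for clash group(s): ",
         paste(sprintf("%s (%d < %d)", low, counts[low], minC),
               collapse = ", "))
  corr <- vapply(gaps, function(x)
    unname(stats::quantile(x, 0.10, type = 7)), numeric(1))
  methods::new("ClashGroupTable", correction = corr, counts = counts)
}

#' Fit peptide-geometry Gaussians
#'
#' Sample mean and standard deviation for the two peptide-bond angles and
#' the N-Cp bond length, with a floor on the standard deviation.
#'
#' @param obs data.frame as returned by \code{\link{peptideGeometry}}
#'   (possibly row-bound over many structures); excluded rows are ignored.
#' @param params parameter list.
#' @param minObs minimum number of observations.
#' @return data.frame with columns \code{name}, \code{mean}, \code{sd}.
#' @export
fitPeptideGaussians <- function(obs, params = defaultParameters(),
                                minObs = 20) {
  obs <- obs[!obs$excluded, , drop = FALSE]
  if (nrow(obs) < minObs)
    stop(sprintf("too few peptide-bond observations (%d < %d)",
                 nrow(obs), minObs))
  flo <- params$peptide$sigma_floor %||% 1e-3
  cols <- c("angle_CA_N_Cp", "angle_CAp_Cp_N", "dist_N_Cp")
  data.frame(name = cols,
             mean = vapply(cols, function(cn) mean(obs[[cn]]), numeric(1)),
             sd = vapply(cols, function(cn)
               max(stats::sd(obs[[cn]]), flo), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# number of chi slots per residue type according to the chi table
nChiSlots <- function(resname, params) {
  sum(params$tables$chi$res == resname)
}

#' Fit the full calibration bundle from a reference set
#'
#' Runs \code{\link{fitClashCorrections}}, fits per-residue-type backbone
#' (phi, psi) densities, the omega density, per-type chi densities and the
#' peptide-geometry Gaussians from the same reference structures.
#'
#' @param refs list of \linkS4class{StructureModel}.
#' @param params parameter list.
#' @param seed integer seed (density center subsampling).
#' @return a \linkS4class{Calibration}.
#' @export
fitCalibration <- function(refs, params = defaultParameters(), seed = 1L) {
  clash <- fitClashCorrections(refs, params)
  phipsi <- list(); chis <- list(); omegas <- numeric()
  pepObs <- NULL
  for (s in refs) {
    t <- backboneTorsions(s, params)
    ok <- !is.na(t@phi) & !is.na(t@psi)
    for (rt in unique(t@residueType[ok])) {
      sel <- ok & t@residueType == rt
      phipsi[[rt]] <- rbind(phipsi[[rt]], cbind(t@phi[sel], t@psi[sel]))
    }
    omegas <- c(omegas, t@omega[!is.na(t@omega)])
    for (rt in unique(t@residueType)) {
      k <- nChiSlots(rt, params)
      if (k == 0) next
      sel <- t@residueType == rt
      m <- t@chi[sel, seq_len(k), drop = FALSE]
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m)) chis[[rt]] <- rbind(chis[[rt]], m)
    }
    pepObs <- rbind(pepObs, peptideGeometry(s, params))
  }
  backbone <- lapply(phipsi, fitTorsionDensity, params = params, seed = seed)
  omega <- fitTorsionDensity(omegas, params = params, seed = seed)
  chi <- lapply(chis, fitTorsionDensity, params = params, seed = seed)
  pep <- fitPeptideGaussians(pepObs, params)
  dens <- methods::new("DensityModel", backbone = backbone, omega = omega,
                       chi = chi, peptide = pep,
                       floor = params$density$floor %||% 1e-12)
  methods::new("Calibration", params = params, clash = clash,
               densities = dens)
}

densToList <- function(d) list(centers = apply(unname(d$centers), 1, c,
                                               simplify = FALSE),
                               kappa = as.numeric(d$kappa),
                               floor = d$floor)

densFromList <- function(l) {
  centers <- do.call(rbind, lapply(l$centers, as.numeric))
  if (is.null(centers)) centers <- matrix(numeric(), 0, length(l$kappa))
  if (ncol(centers) != length(l$kappa)) centers <- t(centers)
  list(centers = centers, kappa = as.numeric(l$kappa), floor = l$floor)
}

#' Write a calibration bundle to a versioned YAML file
#'
#' @param calib a \linkS4class{Calibration}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeCalibration <- function(calib, path) {
  params <- calib@params; params$tables <- NULL
  obj <- list(
    format = "foldgrad-calibration", version = 1L,
    params = params,
    clash = list(correction = as.list(calib@clash@correction),
                 counts = as.list(calib@clash@counts)),
    densities = list(
      backbone = lapply(calib@densities@backbone, densToList),
      omega = densToList(calib@densities@omega),
      chi = lapply(calib@densities@chi, densToList),
      floor = calib@densities@floor),
    peptide = list(name = calib@densities@peptide$name,
                   mean = calib@densities@peptide$mean,
                   sd = calib@densities@peptide$sd))
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a calibration bundle written by \code{\link{writeCalibration}}
#'
#' @param path YAML calibration file.
#' @param params optional parameter list overriding the stored one (tables
#'   are re-attached from the shipped defaults either way).
#' @return a \linkS4class{Calibration}.
#' @export
readCalibration <- function(path, params = NULL) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "foldgrad-calibration"))
    stop("not a calibration file: ", path)
  if (is.null(params)) {
    params <- defaultParameters()
    params <- utils::modifyList(params, obj$params)
    params$tables <- defaultParameters()$tables
  }
  clash <- methods::new("ClashGroupTable",
                        correction = unlist(obj$clash$correction)[
                          clashGroupNames],
                        counts = vapply(obj$clash$counts, as.integer,
                                        integer(1))[clashGroupNames])
  dens <- methods::new("DensityModel",
                       backbone = lapply(obj$densities$backbone,
                                         densFromList),
                       omega = densFromList(obj$densities$omega),
                       chi = lapply(obj$densities$chi, densFromList),
                       peptide = data.frame(name = obj$peptide$name,
                                            mean = obj$peptide$mean,
                                            sd = obj$peptide$sd,
                                            stringsAsFactors = FALSE),
                       floor = obj$densities$floor %||% 1e-12)
  methods::new("Calibration", params = params, clash = clash,
               densities = dens)
}
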