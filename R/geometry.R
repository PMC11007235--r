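# Torsion extraction, the smooth solvent-exposure proxy, peptide-bond
# geometry observations and internal-coordinate forward kinematics.

# minimal per-residue index tables for a bare StructureModel
modelIndexTables <- function(s, params = defaultParameters()) {
  a <- s@atoms
  resIdx <- cumsum(!duplicated(paste(a$chain, a$resno, a$icode, sep = "|")))
  blocks <- split(seq_len(nrow(a)), resIdx)
  torsionIndexTables(a, resIdx, blocks, params)
}

torsionsFromCoords <- function(X, idx, resnames) {
  nres <- nrow(idx$phiIdx)
  evalQuad <- function(q) {
    ok <- !apply(is.na(q), 1, any)
    ang <- rep(NA_real_, nrow(q))
    if (any(ok))
      ang[ok] <- dihedralCore(X[q[ok, 1], , drop = FALSE],
                              X[q[ok, 2], , drop = FALSE],
                              X[q[ok, 3], , drop = FALSE],
                              X[q[ok, 4], , drop = FALSE],
                              grad = FALSE)$angle
    ang
  }
  chi <- matrix(NA_real_, nres, 5)
  for (b in seq_len(nres)) {
    q <- idx$chiIdx[[b]]
    if (nrow(q)) chi[b, seq_len(nrow(q))] <- evalQuad(q)
  }
  methods::new("TorsionSet", phi = evalQuad(idx$phiIdx),
               psi = evalQuad(idx$psiIdx), omega = evalQuad(idx$omegaIdx),
               chi = chi, residueType = resnames,
               index = idx[c("phiIdx", "psiIdx", "omegaIdx", "chiIdx")])
}

#' Backbone torsion angles
#'
#' phi from C(i-1)-N-CA-C, psi from N-CA-C-N(i+1), omega from
#' CA(i-1)-C(i-1)-N-CA; angles in radians wrapped to (-pi, pi], masked (NA)
#' at chain termini and wherever a defining atom is missing.
#'
#' @param s a \linkS4class{StructureModel}.
#' @param params parameter list.
#' @return a \linkS4class{TorsionSet} (chi slots are also filled).
#' @export
backboneTorsions <- function(s, params = defaultParameters()) {
  idx <- modelIndexTables(s, params)
  res <- residues(s)
  torsionsFromCoords(coords(s), idx, res$resname)
}

#' Side-chain chi torsion angles
#'
#' chi angles from the standard atom-quadruple table per residue type (up to
#' five); missing atoms mask the slot. Glycine and alanine have no valid chi.
#'
#' @inheritParams backboneTorsions
#' @return a \linkS4class{TorsionSet}.
#' @export
chiTorsions <- function(s, params = defaultParameters())
  backboneTorsions(s, params)

#' Peptide-bond geometry observations
#'
#' For each pair of consecutive residues in the same chain: the CA-N-Cp and
#' CAp-Cp-N bond angles (radians; p marks the previous residue) and the N-Cp
#' peptide-bond length (Angstrom). Bonds longer than the configured break
#' distance are flagged \code{excluded} and contribute no energy.
#'
#' @inheritParams backboneTorsions
#' @return data.frame with columns \code{resi}, \code{angle_CA_N_Cp},
#'   \code{angle_CAp_Cp_N}, \code{dist_N_Cp}, \code{excluded}.
#' @export
peptideGeometry <- function(s, params = defaultParameters()) {
  idx <- modelIndexTables(s, params)
  peptideGeometryFromCoords(coords(s), idx$peptide, params)
}

peptideGeometryFromCoords <- function(X, pep, params) {
  if (nrow(pep) == 0L)
    return(data.frame(resi = integer(), angle_CA_N_Cp = numeric(),
                      angle_CAp_Cp_N = numeric(), dist_N_Cp = numeric(),
                      excluded = logical()))
  N <- X[pep[, 2], , drop = FALSE]; Cp <- X[pep[, 3], , drop = FALSE]
  CA <- X[pep[, 4], , drop = FALSE]; CAp <- X[pep[, 5], , drop = FALSE]
  d <- rowNorm(N - Cp)
  a1 <- angleCore(CA, N, Cp, grad = FALSE)$angle
  a2 <- angleCore(CAp, Cp, N, grad = FALSE)$angle
  data.frame(resi = pep[, 1], angle_CA_N_Cp = a1, angle_CAp_Cp_N = a2,
             dist_N_Cp = d,
             excluded = d > (params$peptide$break_distance %||% 2.5))
}

# smooth occlusion-based exposure for heavy atoms.
# exposure_i = exp(-kappa * sum_j s(d_ij)), s a falling sigmoid.
# Returns per-atom exposure (NA for hydrogens) plus the pair pieces needed
# to assemble gradients.
exposureCore <- function(at, params, pairs = NULL) {
  X <- at@coords
  heavy <- which(at@index$heavy)
  kap <- params$exposure$kappa
  r0 <- params$exposure$shell_radius
  lam <- params$exposure$sharpness
  cutoff <- r0 + 8 * lam
  n <- nrow(X)
  expo <- rep(NA_real_, n)
  if (!length(heavy)) return(list(exposure = expo, pairs = NULL))
  if (is.null(pairs)) {
    p <- pairsWithin(X[heavy, , drop = FALSE], cutoff)
    i <- heavy[p$i]; j <- heavy[p$j]
    # occlusion counts packing against other residues, not an atom's own
    # covalent neighbourhood
    keep <- at@residueIndex[i] != at@residueIndex[j] &
      !(pairKey(i, j, n) %in% at@index$key12)
    pairs <- list(i = i[keep], j = j[keep], d = p$d[keep])
  }
  sig <- 1 / (1 + exp((pairs$d - r0) / lam))
  S <- rep(0, n)
  if (length(pairs$i)) {
    tab <- rowsum(c(sig, sig), c(pairs$i, pairs$j), reorder = FALSE)
    S[as.integer(rownames(tab))] <- tab[, 1]
  }
  expo[heavy] <- exp(-kap * S[heavy])
  list(exposure = expo, pairs = pairs, sig = sig, kappa = kap, lambda = lam)
}

#' Smooth solvent-exposure proxy
#'
#' A differentiable occlusion measure: each heavy atom's exposure is
#' exp(-kappa * S) where S sums a falling sigmoid of the distances to all
#' neighbouring heavy atoms. An isolated atom reads 1; a densely buried atom
#' approaches 0. Per-residue aggregates are means over the residue's heavy
#' atoms; the side-chain aggregate covers side-chain heavy atoms only (CA is
#' used as a stand-in for glycine).
#'
#' @param table an \linkS4class{AtomTable}.
#' @param params parameter list (exposure kappa, shell radius, sharpness).
#' @return list with \code{atom} (per-atom exposure, NA for hydrogens),
#'   \code{residue} and \code{sidechain} (per-residue aggregates).
#' @export
solventExposure <- function(table, params = defaultParameters()) {
  ec <- exposureCore(table, params)
  n <- nrow(table@coords)
  nres <- nrow(table@residues)
  resAgg <- scAgg <- rep(NA_real_, nres)
  for (b in seq_len(nres)) {
    rows <- table@index$blocks[[b]]
    hv <- rows[table@index$heavy[rows]]
    if (length(hv)) resAgg[b] <- mean(ec$exposure[hv])
    sc <- table@index$sideChain[[b]]
    if (!length(sc)) sc <- rows[table@atomName[rows] == "CA"]
    if (length(sc)) scAgg[b] <- mean(ec$exposure[sc])
  }
  list(atom = ec$exposure, residue = resAgg, sidechain = scAgg)
}

# resolve a torsion specification to radians for residue b
resolveTorsion <- function(type, offsetDeg, b, phi, psi, omega, chi,
                           fallback = c(phi = -57, psi = -47, omega = 180)) {
  off <- deg2rad(offsetDeg)
  base <- switch(type,
    fixed = 0,
    phi = phi[b] %na% deg2rad(fallback[["phi"]]),
    psi = psi[b] %na% deg2rad(fallback[["psi"]]),
    psi_prev = psi[b - 1L] %na% deg2rad(fallback[["psi"]]),
    omega = omega[b] %na% deg2rad(fallback[["omega"]]),
    chi1 = chi[b, 1] %na% pi, chi2 = chi[b, 2] %na% pi,
    chi3 = chi[b, 3] %na% pi, chi4 = chi[b, 4] %na% pi,
    chi5 = chi[b, 5] %na% pi,
    stop("unknown torsion type in topology: ", type))
  wrapAngle(base + off)
}

`%na%` <- function(a, b) if (is.na(a)) b else a

# Sequential internal-coordinate construction of one chain of heavy atoms.
# resnames: three-letter codes; torsions: list(phi, psi, omega, chi) in
# radians (NA allowed -> fallback values). Returns the atom data frame.
buildChainCoords <- function(resnames, torsions, params, chain = "A",
                             geomNoise = NULL) {
  topo <- params$tables$topology
  nres <- length(resnames)
  phi <- torsions$phi %||% rep(NA_real_, nres)
  psi <- torsions$psi %||% rep(NA_real_, nres)
  omega <- torsions$omega %||% rep(NA_real_, nres)
  # the final residue's psi is not recoverable from the structure, so its
  # carbonyl O always uses the fallback value: keeps the build/extract/
  # rebuild cycle exact
  psi[nres] <- NA_real_
  chi <- torsions$chi %||% matrix(NA_real_, nres, 5)
  atoms <- list()
  pos <- list() # pos[[b]][[atomName]] = xyz
  for (b in seq_len(nres)) {
    tt <- topologyFor(topo, resnames[b])
    if (is.na(match(resnames[b], aminoAcids3)))
      stop("unknown residue type: ", resnames[b])
    pos[[b]] <- list()
    for (k in seq_len(nrow(tt))) {
      nm <- tt$atom[k]
      if (b == 1L && nm %in% c("N", "CA", "C")) {
        # seed the global frame with ideal first-residue geometry
        if (nm == "N") xyz <- c(0, 0, 0)
        if (nm == "CA") xyz <- c(1.458, 0, 0)
        if (nm == "C") {
          th <- deg2rad(111.2)
          xyz <- pos[[1]][["CA"]] +
            1.525 * c(cos(pi - th), sin(pi - th), 0)
        }
      } else {
        getp <- function(ref) {
          if (startsWith(ref, "-")) pos[[b - 1L]][[substring(ref, 2)]]
          else pos[[b]][[ref]]
        }
        if (b == 1L && startsWith(tt$p1[k], "-")) next # no previous residue
        p1 <- getp(tt$p1[k]); p2 <- getp(tt$p2[k]); p3 <- getp(tt$p3[k])
        if (is.null(p1) || is.null(p2) || is.null(p3))
          stop("topology parent missing for ", resnames[b], " ", nm)
        tors <- resolveTorsion(tt$tors[k], tt$offsetNum[k], b,
                               phi, psi, omega, chi)
        bond <- tt$bond[k]; ang <- tt$angle[k]
        if (!is.null(geomNoise) && nm %in% c("N", "CA")) {
          # peptide-bond internal coordinates vary in observed structures;
          # the reference generator emulates that spread
          ang <- ang + stats::rnorm(1, 0, geomNoise$angleSD %||% 1.5)
          if (nm == "N")
            bond <- bond + stats::rnorm(1, 0, geomNoise$bondSD %||% 0.01)
        }
        xyz <- nerfPlace(p3, p2, p1, bond, deg2rad(ang), tors)
      }
      pos[[b]][[nm]] <- xyz
      atoms[[length(atoms) + 1L]] <- data.frame(
        chain = chain, resno = b, icode = "", resname = resnames[b],
        atom = nm, element = elementFromName(nm), x = xyz[1], y = xyz[2],
        z = xyz[3], occ = 1, altloc = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, atoms)
}

#' Rebuild coordinates from torsion angles
#'
#' Deterministic sequential placement (natural-extension reference frame)
#' of a single chain from its torsion set and the internal-coordinate
#' topology template: fixed ideal bond lengths and angles, free phi, psi,
#' omega and chi torsions. The first three atoms define the global frame,
#' so the result matches the source structure up to a rigid motion (exactly,
#' for structures built from the same template).
#'
#' @param t a \linkS4class{TorsionSet}.
#' @param params parameter list supplying the topology template.
#' @param chain chain identifier for the rebuilt model.
#' @return a \linkS4class{StructureModel} of heavy atoms.
#' @export
rebuildFromTorsions <- function(t, params = defaultParameters(),
                                chain = "A") {
  atoms <- buildChainCoords(t@residueType,
                            list(phi = t@phi, psi = t@psi, omega = t@omega,
                                 chi = t@chi), params, chain = chain)
  newStructureModel(atoms, provenance = "rebuilt from torsions")
}

# rigid-motion alignment (Kabsch) returning RMSD after superposition
alignedRMSD <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((B0 %*% R - A0)^2)))
}
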