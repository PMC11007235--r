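# Per-atom physical annotation: charges, radii, donor/acceptor typing, the
# covalent bond graph and the torsion/peptide index tables that the energy
# terms consume.

pairKey <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n + hi
}

#' Assign physical annotations to every atom
#'
#' Builds the flat \linkS4class{AtomTable}: partial charges (formal charges
#' split over equivalent atoms), per-element radii, donor/acceptor/sulfur/
#' backbone flags, the covalent bond graph (including detected disulfides)
#' and precomputed torsion and peptide-bond index tables. All lookups come
#' from the configured parameter tables, not from hard-coded values.
#'
#' @param s a \linkS4class{StructureModel} (hydrogens already placed if
#'   hydrogen-bond energies are wanted).
#' @param params parameter list.
#' @param unknownResidue policy for non-standard residue names:
#'   \code{"skip"} drops them with a warning, \code{"error"} aborts.
#' @return an \linkS4class{AtomTable}.
#' @export
assignAtomAnnotations <- function(s, params = defaultParameters(),
                                  unknownResidue = c("skip", "error")) {
  unknownResidue <- match.arg(unknownResidue)
  a <- s@atoms
  known <- a$resname %in% aminoAcids3
  if (any(!known)) {
    bad <- unique(a$resname[!known])
    if (unknownResidue == "error")
      stop("unknown residue name(s): ", paste(bad, collapse = ", "))
    warning("skipping unknown residue name(s): ", paste(bad, collapse = ", "))
    a <- a[known, , drop = FALSE]
  }
  n <- nrow(a)
  resIdx <- if (n) cumsum(!duplicated(paste(a$chain, a$resno, a$icode,
                                            sep = "|"))) else integer()
  resTab <- data.frame(chain = a$chain[!duplicated(resIdx)],
                       resno = a$resno[!duplicated(resIdx)],
                       icode = a$icode[!duplicated(resIdx)],
                       resname = a$resname[!duplicated(resIdx)],
                       stringsAsFactors = FALSE)
  chainIdx <- if (n) match(a$chain, unique(a$chain)) else integer()

  radTab <- unlist(params$radii)
  radius <- unname(radTab[a$element])
  radius[is.na(radius)] <- 1.7

  atab <- params$tables$atoms
  lookupRow <- function(resname, atom) {
    hit <- which(atab$res == resname & atab$atom == atom)
    if (!length(hit)) hit <- which(atab$res == "*" & atab$atom == atom)
    if (length(hit)) hit[1] else NA_integer_
  }
  rows <- mapply(lookupRow, a$resname, a$atom)
  charge <- ifelse(is.na(rows), 0, atab$charge[rows])
  donorHeavyFlag <- ifelse(is.na(rows), FALSE, atab$donor[rows] == 1)
  isAcceptor <- ifelse(is.na(rows), FALSE, atab$acceptor[rows] == 1)
  hybrid <- ifelse(is.na(rows), NA_character_, atab$hybrid[rows])
  antecedentName <- ifelse(is.na(rows), NA_character_, atab$antecedent[rows])
  isSulfur <- a$element == "S"
  isBackbone <- a$atom %in% c(backboneAtoms, "H")

  ## covalent bond graph: topology parents + peptide bonds + hydrogens +
  ## proline ring closure + disulfides
  topo <- params$tables$topology
  htab <- params$tables$hydrogens
  bonds <- list()
  blocks <- split(seq_len(n), resIdx)
  for (b in seq_along(blocks)) {
    rows_ <- blocks[[b]]
    resname <- a$resname[rows_[1]]
    tt <- topologyFor(topo, resname)
    for (k in seq_len(nrow(tt))) {
      if (startsWith(tt$p1[k], "-")) next # inter-residue, handled below
      i <- findAtom(a, rows_, tt$atom[k]); j <- findAtom(a, rows_, tt$p1[k])
      if (!anyNA(c(i, j))) bonds[[length(bonds) + 1L]] <- c(i, j)
    }
    iO <- findAtom(a, rows_, "OXT"); iC <- findAtom(a, rows_, "C")
    if (!anyNA(c(iO, iC))) bonds[[length(bonds) + 1L]] <- c(iO, iC)
    hh <- htab[htab$res == resname, , drop = FALSE]
    for (k in seq_len(nrow(hh))) {
      i <- findAtom(a, rows_, hh$hname[k])
      j <- findAtom(a, rows_, hh$parent[k])
      if (!anyNA(c(i, j))) bonds[[length(bonds) + 1L]] <- c(i, j)
    }
    iH <- findAtom(a, rows_, "H"); iN <- findAtom(a, rows_, "N")
    if (!anyNA(c(iH, iN))) bonds[[length(bonds) + 1L]] <- c(iH, iN)
    if (resname == "PRO") {
      iCD <- findAtom(a, rows_, "CD")
      if (!anyNA(c(iCD, iN))) bonds[[length(bonds) + 1L]] <- c(iCD, iN)
    }
    if (b > 1L) { # peptide bond to the previous residue (same chain)
      prev <- blocks[[b - 1L]]
      if (a$chain[prev[1]] == a$chain[rows_[1]]) {
        iCp <- findAtom(a, prev, "C")
        if (!anyNA(c(iN, iCp))) {
          X <- as.matrix(a[c(iN, iCp), c("x", "y", "z")])
          if (sqrt(sum((X[1, ] - X[2, ])^2)) < 2.0)
            bonds[[length(bonds) + 1L]] <- c(iN, iCp)
        }
      }
    }
  }
  ssPairs <- matrix(integer(), 0, 2)
  sg <- which(a$atom == "SG" & a$resname == "CYS")
  if (length(sg) > 1L) {
    X <- as.matrix(a[sg, c("x", "y", "z")])
    D <- as.matrix(stats::dist(X))
    hit <- which(upper.tri(D) & D <= (params$disulfide$cutoff %||% 2.5),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      ssPairs <- cbind(sg[hit[, 1]], sg[hit[, 2]])
      for (k in seq_len(nrow(ssPairs)))
        bonds[[length(bonds) + 1L]] <- ssPairs[k, ]
    }
  }
  bondMat <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(), 0, 2)

  ## 1-2 and 1-3 pair keys
  adj <- vector("list", n)
  for (k in seq_len(nrow(bondMat))) {
    i <- bondMat[k, 1]; j <- bondMat[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  key12 <- if (nrow(bondMat)) unique(pairKey(bondMat[, 1], bondMat[, 2], n))
           else numeric()
  k13 <- numeric()
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) > 1L) {
      cmb <- utils::combn(nb, 2L)
      k13 <- c(k13, pairKey(cmb[1, ], cmb[2, ], n))
    }
  }
  key13 <- setdiff(unique(k13), key12)

  ## donor hydrogens: H atoms bonded to a donor heavy atom
  donorHeavy <- rep(NA_integer_, n)
  isDonorH <- rep(FALSE, n)
  for (i in which(a$element == "H")) {
    nb <- adj[[i]]
    hv <- nb[donorHeavyFlag[nb]]
    if (length(hv)) { isDonorH[i] <- TRUE; donorHeavy[i] <- hv[1] }
  }
  acceptorAntecedent <- rep(NA_integer_, n)
  for (i in which(isAcceptor)) {
    rows_ <- blocks[[resIdx[i]]]
    acceptorAntecedent[i] <- findAtom(a, rows_, antecedentName[i])
  }
  # acceptors without a locatable antecedent cannot define lone-pair geometry
  isAcceptor[is.na(acceptorAntecedent) & isAcceptor] <- FALSE

  idx <- list(bonds = bondMat, key12 = key12, key13 = key13,
              ssPairs = ssPairs, adjacency = adj,
              heavy = a$element != "H", hybrid = hybrid)
  idx <- c(idx, torsionIndexTables(a, resIdx, blocks, params))

  methods::new("AtomTable",
               coords = unname(as.matrix(a[, c("x", "y", "z")])),
               charge = as.numeric(charge), radius = radius,
               isDonorH = isDonorH, isAcceptor = isAcceptor,
               isSulfur = isSulfur, isBackbone = isBackbone,
               residueIndex = as.integer(resIdx),
               chainIndex = as.integer(chainIdx),
               element = a$element, atomName = a$atom, resname = a$resname,
               donorHeavy = donorHeavy,
               acceptorAntecedent = acceptorAntecedent,
               residues = resTab, index = idx)
}

# phi/psi/omega quadruples, chi quadruples, peptide-bond index tables and
# side-chain membership, all as atom indices into the table
torsionIndexTables <- function(a, resIdx, blocks, params) {
  nres <- length(blocks)
  phiIdx <- psiIdx <- omegaIdx <- matrix(NA_integer_, nres, 4)
  chiIdx <- vector("list", nres)
  chiRot <- vector("list", nres)
  scAtoms <- vector("list", nres)
  pep <- matrix(NA_integer_, 0, 5) # resi, N, Cp, CA, CAp
  chiTab <- params$tables$chi
  get <- function(b, name) if (b < 1L || b > nres) NA_integer_ else
    findAtom(a, blocks[[b]], name)
  sameChain <- function(b1, b2) {
    b1 >= 1L && b2 >= 1L && b1 <= nres && b2 <= nres &&
      a$chain[blocks[[b1]][1]] == a$chain[blocks[[b2]][1]]
  }
  for (b in seq_len(nres)) {
    N <- get(b, "N"); CA <- get(b, "CA"); C <- get(b, "C")
    prevOK <- b > 1L && sameChain(b - 1L, b)
    nextOK <- b < nres && sameChain(b, b + 1L)
    Cp <- if (prevOK) get(b - 1L, "C") else NA_integer_
    CAp <- if (prevOK) get(b - 1L, "CA") else NA_integer_
    Nn <- if (nextOK) get(b + 1L, "N") else NA_integer_
    phiIdx[b, ] <- c(Cp, N, CA, C)
    psiIdx[b, ] <- c(N, CA, C, Nn)
    omegaIdx[b, ] <- c(CAp, Cp, N, CA)
    if (prevOK && !anyNA(c(N, Cp, CA, CAp)))
      pep <- rbind(pep, c(b, N, Cp, CA, CAp))
    resname <- a$resname[blocks[[b]][1]]
    ct <- chiTab[chiTab$res == resname, , drop = FALSE]
    if (nrow(ct)) {
      m <- matrix(NA_integer_, nrow(ct), 4)
      for (k in seq_len(nrow(ct)))
        m[k, ] <- c(get(b, ct$a1[k]), get(b, ct$a2[k]),
                    get(b, ct$a3[k]), get(b, ct$a4[k]))
      chiIdx[[b]] <- m
      chiRot[[b]] <- ct$rotatable == 1
    } else {
      chiIdx[[b]] <- matrix(NA_integer_, 0, 4)
      chiRot[[b]] <- logical()
    }
    rows_ <- blocks[[b]]
    scAtoms[[b]] <- rows_[!(a$atom[rows_] %in% c(backboneAtoms, "H")) &
                            a$element[rows_] != "H"]
  }
  list(phiIdx = phiIdx, psiIdx = psiIdx, omegaIdx = omegaIdx,
       chiIdx = chiIdx, chiRotatable = chiRot, peptide = pep,
       sideChain = scAtoms, blocks = blocks)
}
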