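# Internal energy terms, part 2: exposure-coupled terms and the
# density-based entropy/violation terms.

termSolvationVdw <- function(at, X, params, ec, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  cPol <- residueCoeff(at, params, "c_polar") *
    params$weights$solvation_polar
  cHyd <- residueCoeff(at, params, "c_hydrophobic") *
    params$weights$solvation_hydrophobic
  cVdw <- residueCoeff(at, params, "c_vdw") * params$weights$vdw
  ePol <- eHyd <- eVdw <- rep(0, nres)
  dEde <- rep(0, n) # accumulated d(total)/d(exposure_atom)
  for (b in seq_len(nres)) {
    rows <- at@index$blocks[[b]]
    hv <- rows[at@index$heavy[rows]]
    if (!length(hv)) next
    m <- mean(ec$exposure[hv])
    ePol[b] <- cPol[b] * m
    eHyd[b] <- cHyd[b] * m
    eVdw[b] <- cVdw[b] * mean(1 - ec$exposure[hv])
    if (grad)
      dEde[hv] <- dEde[hv] + (cPol[b] + cHyd[b] - cVdw[b]) / length(hv)
  }
  list(polar = ePol, hydrophobic = eHyd, vdw = eVdw, dEde = dEde)
}

# side-chain entropy with the full-cost gate: an amino-acid-specific cost
# S(type), scaled by side-chain burial unless hydrogen bonds, strong
# electrostatic pairs or disulfides lock the side chain. Each interaction
# class feeds its own smooth gate channel; the channels combine as
# g = 1 - prod(1 - g_x) so any one firing channel forces the full cost.
termSidechainEntropy <- function(at, X, params, ec, elec, hb, ss,
                                 grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  w <- params$weights$entropy_sidechain
  S <- residueCoeff(at, params, "s_entropy") * w
  res <- rep(0, nres); G <- matrix(0, n, 3)
  dEde <- rep(0, n)
  if (all(S == 0)) return(list(res = res, grad = G, dEde = dEde))
  sp <- params$sidechain_entropy
  thrHB <- sp$hbond_threshold %||% 0.3
  tauHB <- sp$hbond_tau %||% 0.08
  thrEL <- abs(sp$strong_elec_threshold %||% 1)
  tauEL <- sp$gate_tau %||% 0.25
  thrSS <- sp$disulfide_threshold %||% 0.5
  tauSS <- sp$disulfide_tau %||% 0.1
  scFlag <- rep(FALSE, n)
  for (b in seq_len(nres)) scFlag[at@index$sideChain[[b]]] <- TRUE
  # per-residue interaction magnitudes, one per channel
  Ahb <- Ael <- Ass <- rep(0, nres)
  hbSC <- NULL
  if (nrow(hb$pairs)) {
    p <- hb$pairs
    dhSC <- scFlag[p$dh]; aSC <- scFlag[p$a]
    for (k in seq_len(nrow(p))) {
      if (dhSC[k]) Ahb[at@residueIndex[p$dh[k]]] <-
          Ahb[at@residueIndex[p$dh[k]]] - p$e[k]
      if (aSC[k]) Ahb[at@residueIndex[p$a[k]]] <-
          Ahb[at@residueIndex[p$a[k]]] - p$e[k]
    }
    hbSC <- list(p = p, dhSC = dhSC, aSC = aSC)
  }
  elSC <- NULL
  if (nrow(elec$pairs)) {
    p <- elec$pairs
    iSC <- scFlag[p$i]; jSC <- scFlag[p$j]
    amt <- softplus(-p$e)
    for (k in seq_len(nrow(p))) {
      if (iSC[k]) Ael[at@residueIndex[p$i[k]]] <-
          Ael[at@residueIndex[p$i[k]]] + amt[k]
      if (jSC[k]) Ael[at@residueIndex[p$j[k]]] <-
          Ael[at@residueIndex[p$j[k]]] + amt[k]
    }
    elSC <- list(p = p, iSC = iSC, jSC = jSC)
  }
  ssSC <- NULL
  if (nrow(ss$pairs)) {
    p <- ss$pairs
    for (k in seq_len(nrow(p))) {
      Ass[at@residueIndex[p$i[k]]] <- Ass[at@residueIndex[p$i[k]]] - p$e[k]
      Ass[at@residueIndex[p$j[k]]] <- Ass[at@residueIndex[p$j[k]]] - p$e[k]
    }
    ssSC <- list(p = p)
  }
  gHB <- sigmoid((Ahb - thrHB) / tauHB)
  gEL <- sigmoid((Ael - thrEL) / tauEL)
  gSS <- sigmoid((Ass - thrSS) / tauSS)
  g <- 1 - (1 - gHB) * (1 - gEL) * (1 - gSS)
  expoSC <- rep(0, nres)
  for (b in seq_len(nres)) {
    sc <- at@index$sideChain[[b]]
    if (length(sc)) expoSC[b] <- mean(ec$exposure[sc])
  }
  scale <- 1 - (1 - g) * expoSC
  res <- S * scale
  if (grad) {
    for (b in seq_len(nres)) {
      sc <- at@index$sideChain[[b]]
      if (!length(sc) || S[b] == 0) next
      dEde[sc] <- dEde[sc] - S[b] * (1 - g[b]) / length(sc)
    }
    # dE/dA_x = S * expoSC * dg/dA_x with
    # dg/dA_x = g_x'(A_x) * prod over the other channels of (1 - g_y)
    dEdAhb <- S * expoSC * gHB * (1 - gHB) / tauHB * (1 - gEL) * (1 - gSS)
    dEdAel <- S * expoSC * gEL * (1 - gEL) / tauEL * (1 - gHB) * (1 - gSS)
    dEdAss <- S * expoSC * gSS * (1 - gSS) / tauSS * (1 - gHB) * (1 - gEL)
    if (!is.null(hbSC) && !is.null(hb$pairGrads)) {
      p <- hbSC$p; pg <- hb$pairGrads
      ri <- at@residueIndex
      mult <- ifelse(hbSC$dhSC, dEdAhb[ri[p$dh]], 0) +
        ifelse(hbSC$aSC, dEdAhb[ri[p$a]], 0)
      cf <- -mult # dA/de = -1 for hydrogen-bond contributions
      use <- cf != 0
      if (any(use)) {
        G <- scatterAdd(G, p$h[use], pg$Gh[use, , drop = FALSE] * cf[use])
        G <- scatterAdd(G, p$a[use], pg$Ga[use, , drop = FALSE] * cf[use])
        G <- scatterAdd(G, p$dh[use], pg$Gdh[use, , drop = FALSE] * cf[use])
        G <- scatterAdd(G, pg$aa[use], pg$Gaa[use, , drop = FALSE] * cf[use])
      }
    }
    if (!is.null(elSC) && !is.null(elec$pairs$dEdd)) {
      p <- elSC$p
      ri <- at@residueIndex
      mult <- ifelse(elSC$iSC, dEdAel[ri[p$i]], 0) +
        ifelse(elSC$jSC, dEdAel[ri[p$j]], 0)
      cf <- mult * (-softplusGrad(-p$e)) * p$dEdd # dA/de = -softplus'(-e)
      use <- cf != 0
      if (any(use)) G <- addDistGrad(G, p$i[use], p$j[use], X, cf[use])
    }
    if (!is.null(ssSC) && !is.null(ss$pairGrads)) {
      p <- ssSC$p; pg <- ss$pairGrads
      ri <- at@residueIndex
      mult <- dEdAss[ri[p$i]] + dEdAss[ri[p$j]]
      cf <- -mult # dA/de = -1
      use <- cf != 0
      if (any(use)) {
        G <- scatterAdd(G, p$i[use], pg$Gi[use, , drop = FALSE] * cf[use])
        G <- scatterAdd(G, p$j[use], pg$Gj[use, , drop = FALSE] * cf[use])
        okcb <- use & !is.na(pg$cbi)
        if (any(okcb))
          G <- scatterAdd(G, pg$cbi[okcb],
                          pg$Gcbi[okcb, , drop = FALSE] * cf[okcb])
        okcb <- use & !is.na(pg$cbj)
        if (any(okcb))
          G <- scatterAdd(G, pg$cbj[okcb],
                          pg$Gcbj[okcb, , drop = FALSE] * cf[okcb])
      }
    }
  }
  list(res = res, grad = G, dEde = dEde, gate = g,
       A = Ahb + Ael + Ass)
}

## ---- density-based terms ---------------------------------------------

# log-density upper bound of a product von Mises kernel mixture
densityLogMax <- function(dens) {
  sum(dens$kappa - log(2 * pi) - logBesselI0(dens$kappa))
}

termBackboneEntropy <- function(at, X, params, dens, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  res <- rep(0, nres); G <- matrix(0, n, 3)
  w1 <- params$weights$entropy_backbone_omega
  w2 <- params$weights$entropy_backbone_phipsi
  idx <- at@index
  # omega component
  om <- idx$omegaIdx
  okO <- !apply(is.na(om), 1, any)
  if (any(okO) && w1 != 0) {
    dc <- dihedralCore(X[om[okO, 1], , drop = FALSE],
                       X[om[okO, 2], , drop = FALSE],
                       X[om[okO, 3], , drop = FALSE],
                       X[om[okO, 4], , drop = FALSE], grad = grad)
    ev <- evalTorsionDensity(dens@omega, dc$angle, grad = grad)
    res[okO] <- res[okO] + w1 * (-ev$logDensity)
    if (grad) {
      cf <- -w1 * ev$grad[, 1]
      G <- scatterAdd(G, om[okO, 1], dc$g1 * cf)
      G <- scatterAdd(G, om[okO, 2], dc$g2 * cf)
      G <- scatterAdd(G, om[okO, 3], dc$g3 * cf)
      G <- scatterAdd(G, om[okO, 4], dc$g4 * cf)
    }
  }
  # phi/psi component, per residue type
  ph <- idx$phiIdx; ps <- idx$psiIdx
  okB <- !apply(is.na(ph), 1, any) & !apply(is.na(ps), 1, any)
  types <- at@residues$resname
  if (any(okB) && w2 != 0) {
    missing <- setdiff(unique(types[okB]), names(dens@backbone))
    if (length(missing))
      stop("no fitted backbone density for residue type(s): ",
           paste(missing, collapse = ", "))
    dcP <- dihedralCore(X[ph[okB, 1], , drop = FALSE],
                        X[ph[okB, 2], , drop = FALSE],
                        X[ph[okB, 3], , drop = FALSE],
                        X[ph[okB, 4], , drop = FALSE], grad = grad)
    dcS <- dihedralCore(X[ps[okB, 1], , drop = FALSE],
                        X[ps[okB, 2], , drop = FALSE],
                        X[ps[okB, 3], , drop = FALSE],
                        X[ps[okB, 4], , drop = FALSE], grad = grad)
    which_ <- which(okB)
    for (rt in unique(types[okB])) {
      sel <- which(types[which_] == rt)
      ev <- evalTorsionDensity(dens@backbone[[rt]],
                               cbind(dcP$angle[sel], dcS$angle[sel]),
                               grad = grad)
      res[which_[sel]] <- res[which_[sel]] + w2 * (-ev$logDensity)
      if (grad) {
        cfP <- -w2 * ev$grad[, 1]; cfS <- -w2 * ev$grad[, 2]
        G <- scatterAdd(G, ph[which_[sel], 1], dcP$g1[sel, , drop = FALSE] * cfP)
        G <- scatterAdd(G, ph[which_[sel], 2], dcP$g2[sel, , drop = FALSE] * cfP)
        G <- scatterAdd(G, ph[which_[sel], 3], dcP$g3[sel, , drop = FALSE] * cfP)
        G <- scatterAdd(G, ph[which_[sel], 4], dcP$g4[sel, , drop = FALSE] * cfP)
        G <- scatterAdd(G, ps[which_[sel], 1], dcS$g1[sel, , drop = FALSE] * cfS)
        G <- scatterAdd(G, ps[which_[sel], 2], dcS$g2[sel, , drop = FALSE] * cfS)
        G <- scatterAdd(G, ps[which_[sel], 3], dcS$g3[sel, , drop = FALSE] * cfS)
        G <- scatterAdd(G, ps[which_[sel], 4], dcS$g4[sel, , drop = FALSE] * cfS)
      }
    }
  }
  list(res = res, grad = G)
}

termSidechainViolation <- function(at, X, params, dens, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  res <- rep(0, nres); G <- matrix(0, n, 3)
  wTab <- residueCoeff(at, params, "w_scv") *
    params$weights$sidechain_violation
  types <- at@residues$resname
  for (b in seq_len(nres)) {
    q <- at@index$chiIdx[[b]]
    if (nrow(q) == 0L || wTab[b] == 0) next
    if (any(is.na(q))) next # masked slots: no violation contribution
    rt <- types[b]
    dn <- dens@chi[[rt]]
    if (is.null(dn))
      stop("no fitted chi density for residue type: ", rt)
    dc <- dihedralCore(X[q[, 1], , drop = FALSE], X[q[, 2], , drop = FALSE],
                       X[q[, 3], , drop = FALSE], X[q[, 4], , drop = FALSE],
                       grad = grad)
    ev <- evalTorsionDensity(dn, matrix(dc$angle, nrow = 1), grad = grad)
    off <- log(exp(densityLogMax(dn)) + (dn$floor %||% 1e-12))
    res[b] <- wTab[b] * (off - ev$logDensity)
    if (grad) {
      for (k in seq_len(nrow(q))) {
        cf <- -wTab[b] * ev$grad[1, k]
        G <- scatterAdd(G, q[k, 1], dc$g1[k, , drop = FALSE] * cf)
        G <- scatterAdd(G, q[k, 2], dc$g2[k, , drop = FALSE] * cf)
        G <- scatterAdd(G, q[k, 3], dc$g3[k, , drop = FALSE] * cf)
        G <- scatterAdd(G, q[k, 4], dc$g4[k, , drop = FALSE] * cf)
      }
    }
  }
  list(res = res, grad = G)
}

termPeptideViolation <- function(at, X, params, dens, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  res <- rep(0, nres); G <- matrix(0, n, 3)
  pep <- at@index$peptide
  w <- params$weights$peptide_violation
  if (nrow(pep) == 0L || w == 0) return(list(res = res, grad = G))
  gp <- dens@peptide
  mu <- stats::setNames(gp$mean, gp$name)
  sg <- stats::setNames(gp$sd, gp$name)
  N <- X[pep[, 2], , drop = FALSE]; Cp <- X[pep[, 3], , drop = FALSE]
  CA <- X[pep[, 4], , drop = FALSE]; CAp <- X[pep[, 5], , drop = FALSE]
  d <- rowNorm(N - Cp)
  keep <- d <= (params$peptide$break_distance %||% 2.5)
  if (!any(keep)) return(list(res = res, grad = G))
  a1 <- angleCore(CA, N, Cp, grad = grad)
  a2 <- angleCore(CAp, Cp, N, grad = grad)
  z1 <- (a1$angle - mu[["angle_CA_N_Cp"]]) / sg[["angle_CA_N_Cp"]]
  z2 <- (a2$angle - mu[["angle_CAp_Cp_N"]]) / sg[["angle_CAp_Cp_N"]]
  z3 <- (d - mu[["dist_N_Cp"]]) / sg[["dist_N_Cp"]]
  v <- w * (z1^2 + z2^2 + z3^2) / 2
  v[!keep] <- 0
  res <- res + rowsumInto(nres, pep[, 1], v)
  if (grad) {
    k <- which(keep)
    cf1 <- w * z1[k] / sg[["angle_CA_N_Cp"]]
    G <- scatterAdd(G, pep[k, 4], a1$ga[k, , drop = FALSE] * cf1)
    G <- scatterAdd(G, pep[k, 2], a1$gb[k, , drop = FALSE] * cf1)
    G <- scatterAdd(G, pep[k, 3], a1$gc[k, , drop = FALSE] * cf1)
    cf2 <- w * z2[k] / sg[["angle_CAp_Cp_N"]]
    G <- scatterAdd(G, pep[k, 5], a2$ga[k, , drop = FALSE] * cf2)
    G <- scatterAdd(G, pep[k, 3], a2$gb[k, , drop = FALSE] * cf2)
    G <- scatterAdd(G, pep[k, 2], a2$gc[k, , drop = FALSE] * cf2)
    cf3 <- w * z3[k] / sg[["dist_N_Cp"]]
    G <- addDistGrad(G, pep[k, 2], pep[k, 3], X, cf3)
  }
  list(res = res, grad = G)
}

rowsumInto <- function(nres, idx, val) {
  v <- rep(0, nres)
  tab <- rowsum(val, idx, reorder = FALSE)
  v[as.integer(rownames(tab))] <- tab[, 1]
  v
}
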