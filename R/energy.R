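# Internal energy-term evaluation. Every term returns its per-residue
# energies (already weighted) and accumulates the analytic gradient of its
# total with respect to all atom coordinates. The public wrappers and the
# aggregator live in energy-terms.R / total_energy.R.

# scatter pair-distance derivative dE/dd into the coordinate gradient
addDistGrad <- function(G, i, j, X, dEdd) {
  if (!length(i)) return(G)
  diff <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  d <- pmax(rowNorm(diff), 1e-12)
  u <- diff / d
  G <- scatterAdd(G, i, u * dEdd)
  scatterAdd(G, j, -u * dEdd)
}

halfSplit <- function(nres, resI, resJ, e) {
  v <- rep(0, nres)
  tab <- rowsum(c(e / 2, e / 2), c(resI, resJ), reorder = FALSE)
  v[as.integer(rownames(tab))] <- tab[, 1]
  v
}

## ---- electrostatics (screened Coulomb) --------------------------------

termElectrostatics <- function(at, X, params, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  w <- params$weights$electrostatics
  res <- rep(0, nres); G <- matrix(0, n, 3)
  pairsOut <- data.frame(i = integer(), j = integer(), e = numeric())
  ch <- which(at@charge != 0)
  if (length(ch) >= 2L) {
    p <- pairsWithin(X[ch, , drop = FALSE],
                     params$electrostatics$cutoff %||% 12)
    i <- ch[p$i]; j <- ch[p$j]; d <- p$d
    keep <- at@residueIndex[i] != at@residueIndex[j]
    keys <- pairKey(i, j, n)
    keep <- keep & !(keys %in% at@index$key12) & !(keys %in% at@index$key13)
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    if (length(i)) {
      minD <- params$electrostatics$min_distance %||% 1e-3
      if (any(d < minD)) {
        warning("electrostatic pair distance clamped to ", minD, " Angstrom")
        d <- pmax(d, minD)
      }
      K <- debyeHuckelKappa(params$physical$ionic_strength,
                            params$physical$temperature)
      C0 <- params$physical$coulomb_constant %||% 332
      eps <- params$physical$dielectric
      e <- w * C0 * at@charge[i] * at@charge[j] / (eps * d) * exp(-d * K)
      res <- halfSplit(nres, at@residueIndex[i], at@residueIndex[j], e)
      if (grad) G <- addDistGrad(G, i, j, X, -e * (1 / d + K))
      pairsOut <- data.frame(i = i, j = j, e = e)
      if (grad) { # pair-level dE/dd retained for the entropy gate
        pairsOut$dEdd <- -e * (1 / d + K)
        pairsOut$d <- d
      }
    }
  }
  list(res = res, grad = G, pairs = pairsOut)
}

## ---- hydrogen bonds ---------------------------------------------------

# smooth distance well (minimum -1 at d0), geometric cosine-power factor on
# the D-H...A angle and a Gaussian lone-pair factor on the H...A-antecedent
# angle; soft-min assignment of each hydrogen to its best acceptor
termHbond <- function(at, X, params, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  res <- rep(0, nres); G <- matrix(0, n, 3)
  empty <- data.frame(h = integer(), dh = integer(), a = integer(),
                      e = numeric())
  hp <- params$hbond
  w <- params$weights$hbond
  hs <- which(at@isDonorH); ac <- which(at@isAcceptor)
  if (!length(hs) || !length(ac) || w == 0)
    return(list(res = res, grad = G, pairs = empty, pairGrads = NULL))
  cand <- list()
  for (h in hs) {
    dv <- sqrt(colSums((t(X[ac, , drop = FALSE]) - X[h, ])^2))
    near <- ac[dv <= hp$cutoff]
    dh <- at@donorHeavy[h]
    near <- near[near != dh]
    if (!length(near)) next
    keys <- pairKey(rep(h, length(near)), near, n)
    keysD <- pairKey(rep(dh, length(near)), near, n)
    bad <- keys %in% at@index$key12 | keys %in% at@index$key13 |
      keysD %in% at@index$key12 | keysD %in% at@index$key13
    near <- near[!bad]
    if (length(near))
      cand[[length(cand) + 1L]] <- cbind(h, dh, near)
  }
  if (!length(cand))
    return(list(res = res, grad = G, pairs = empty, pairGrads = NULL))
  cand <- do.call(rbind, cand)
  h <- cand[, 1]; dh <- cand[, 2]; a <- cand[, 3]
  aa <- at@acceptorAntecedent[a]
  Xh <- X[h, , drop = FALSE]; Xa <- X[a, , drop = FALSE]
  Xdh <- X[dh, , drop = FALSE]; Xaa <- X[aa, , drop = FALSE]
  dvec <- Xh - Xa
  d <- pmax(rowNorm(dvec), 1e-9)
  gD <- -(d - hp$d_optimal) / hp$d_sigma^2
  fdist <- -exp(-(d - hp$d_optimal)^2 / (2 * hp$d_sigma^2))
  thDHA <- angleCore(Xdh, Xh, Xa, grad = grad)
  cth <- cos(thDHA$angle)
  base <- (1 - cth) / 2
  fdha <- base^hp$dha_power
  thAcc <- angleCore(Xh, Xa, Xaa, grad = grad)
  opt <- ifelse(at@index$hybrid[a] %in% "sp3",
                deg2rad(hp$lp_optimal_sp3), deg2rad(hp$lp_optimal_sp2))
  sLP <- deg2rad(hp$lp_sigma_deg)
  flp <- exp(-(thAcc$angle - opt)^2 / (2 * sLP^2))
  e <- w * fdist * fdha * flp

  # soft-min over acceptors of each hydrogen
  tau <- hp$softmin_tau %||% 0.1
  m <- rep(1, length(e))        # d(E_H)/d(e_pair)
  eh <- e                        # softly assigned pair energies
  for (hh in unique(h)) {
    sel <- which(h == hh)
    if (length(sel) == 1L) next
    z <- exp((-e[sel] + max(-e[sel])) / tau)
    u <- z / sum(z)
    EH <- sum(u * e[sel])
    eh[sel] <- u * e[sel]
    m[sel] <- u * (1 - (e[sel] - EH) / tau)
  }
  res <- halfSplit(nres, at@residueIndex[h], at@residueIndex[a], eh)
  if (grad) {
    # chain rule: total d/dx = sum_pairs m_pair * d(e_pair)/dx
    dedd <- w * (fdist * gD) * fdha * flp
    G <- addDistGrad(G, h, a, X, m * dedd)
    dfdth <- hp$dha_power * base^(hp$dha_power - 1) * sin(thDHA$angle) / 2
    cf <- m * w * fdist * dfdth * flp
    G <- scatterAdd(G, dh, thDHA$ga * cf)
    G <- scatterAdd(G, h, thDHA$gb * cf)
    G <- scatterAdd(G, a, thDHA$gc * cf)
    dflp <- -flp * (thAcc$angle - opt) / sLP^2
    cf2 <- m * w * fdist * fdha * dflp
    G <- scatterAdd(G, h, thAcc$ga * cf2)
    G <- scatterAdd(G, a, thAcc$gb * cf2)
    G <- scatterAdd(G, aa, thAcc$gc * cf2)
  }
  pairs <- data.frame(h = h, dh = dh, a = a, e = eh)
  pg <- NULL
  if (grad) {
    dedd <- w * (fdist * gD) * fdha * flp
    dfdth <- hp$dha_power * base^(hp$dha_power - 1) * sin(thDHA$angle) / 2
    dflp <- -flp * (thAcc$angle - opt) / sLP^2
    u <- dvec / d
    pg <- list(
      m = m, aa = aa,
      Gh = u * dedd + thDHA$gb * (w * fdist * dfdth * flp) +
        thAcc$ga * (w * fdist * fdha * dflp),
      Ga = -u * dedd + thDHA$gc * (w * fdist * dfdth * flp) +
        thAcc$gb * (w * fdist * fdha * dflp),
      Gdh = thDHA$ga * (w * fdist * dfdth * flp),
      Gaa = thAcc$gc * (w * fdist * fdha * dflp))
  }
  list(res = res, grad = G, pairs = pairs, pairGrads = pg)
}

## ---- disulfide bonds --------------------------------------------------

termDisulfide <- function(at, X, params, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  res <- rep(0, nres); G <- matrix(0, n, 3)
  empty <- data.frame(i = integer(), j = integer(), e = numeric())
  ss <- at@index$ssPairs
  w <- params$weights$disulfide
  if (nrow(ss) == 0L || w == 0)
    return(list(res = res, grad = G, pairs = empty, pairGrads = NULL))
  dp <- params$disulfide
  i <- ss[, 1]; j <- ss[, 2]
  d <- rowNorm(X[i, , drop = FALSE] - X[j, , drop = FALSE])
  inRange <- d <= dp$cutoff
  i <- i[inRange]; j <- j[inRange]; d <- d[inRange]
  if (!length(i))
    return(list(res = res, grad = G, pairs = empty, pairGrads = NULL))
  gauss <- exp(-(d - dp$d_optimal)^2 / (2 * dp$d_sigma^2))
  # chi_SS from CB-SG-SG-CB where both CB atoms exist
  cbi <- cbj <- rep(NA_integer_, length(i))
  for (k in seq_along(i)) {
    cbi[k] <- findAtomIdx(at, at@residueIndex[i[k]], "CB")
    cbj[k] <- findAtomIdx(at, at@residueIndex[j[k]], "CB")
  }
  hasChi <- !is.na(cbi) & !is.na(cbj)
  geom <- rep(1, length(i)); dgeom <- rep(0, length(i))
  dih <- NULL
  if (any(hasChi)) {
    dih <- dihedralCore(X[cbi[hasChi], , drop = FALSE],
                        X[i[hasChi], , drop = FALSE],
                        X[j[hasChi], , drop = FALSE],
                        X[cbj[hasChi], , drop = FALSE], grad = grad)
    s2 <- sin(dih$angle)^2
    geom[hasChi] <- 0.5 * (1 + s2)
    dgeom[hasChi] <- 0.5 * sin(2 * dih$angle)
  }
  e <- -w * gauss * geom
  res <- halfSplit(nres, at@residueIndex[i], at@residueIndex[j], e)
  pg <- NULL
  if (grad) {
    dEdd <- -w * gauss * (-(d - dp$d_optimal) / dp$d_sigma^2) * geom
    G <- addDistGrad(G, i, j, X, dEdd)
    diff <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    u <- diff / pmax(rowNorm(diff), 1e-12)
    # pair-level gradient blocks, retained for the entropy gate
    m <- length(i)
    pg <- list(cbi = cbi, cbj = cbj,
               Gi = u * dEdd, Gj = -u * dEdd,
               Gcbi = matrix(0, m, 3), Gcbj = matrix(0, m, 3))
    if (any(hasChi)) {
      cf <- (-w * gauss * dgeom)[hasChi]
      G <- scatterAdd(G, cbi[hasChi], dih$g1 * cf)
      G <- scatterAdd(G, i[hasChi], dih$g2 * cf)
      G <- scatterAdd(G, j[hasChi], dih$g3 * cf)
      G <- scatterAdd(G, cbj[hasChi], dih$g4 * cf)
      pg$Gcbi[hasChi, ] <- dih$g1 * cf
      pg$Gi[hasChi, ] <- pg$Gi[hasChi, , drop = FALSE] + dih$g2 * cf
      pg$Gj[hasChi, ] <- pg$Gj[hasChi, , drop = FALSE] + dih$g3 * cf
      pg$Gcbj[hasChi, ] <- dih$g4 * cf
    }
  }
  list(res = res, grad = G, pairs = data.frame(i = i, j = j, e = e),
       pairGrads = pg)
}

findAtomIdx <- function(at, resI, name) {
  rows <- at@index$blocks[[resI]]
  hit <- rows[at@atomName[rows] == name]
  if (length(hit)) hit[1] else NA_integer_
}

## ---- clash penalty ----------------------------------------------------

termClash <- function(at, X, params, clashTable, grad = TRUE) {
  n <- nrow(X); nres <- nrow(at@residues)
  res <- rep(0, nres); G <- matrix(0, n, 3)
  cp <- clashPairs(at, X, params)
  if (!nrow(cp)) return(list(res = res, grad = G))
  w <- params$weights$clash
  slope <- params$clash$slope %||% 10
  tg <- clashTable@correction[cp$group]
  gap <- cp$d - (at@radius[cp$i] + at@radius[cp$j])
  # boundary pairs score exactly w (zero exponent); the tiny tolerance
  # keeps the gate stable against round-off at the threshold itself
  active <- gap <= tg + 1e-9
  if (!any(active) || w == 0) return(list(res = res, grad = G))
  i <- cp$i[active]; j <- cp$j[active]
  e <- w * exp(slope * (tg[active] - gap[active]))
  if (isTRUE(params$clash$continuous)) e <- e - w
  res <- halfSplit(nres, at@residueIndex[i], at@residueIndex[j], e)
  if (grad) {
    ex <- w * exp(slope * (tg[active] - gap[active]))
    G <- addDistGrad(G, i, j, X, -slope * ex)
  }
  list(res = res, grad = G)
}

## ---- exposure-coupled terms (solvation, vdW, side-chain entropy) ------

residueCoeff <- function(at, params, column) {
  rt <- params$tables$residues
  rt[[column]][match(at@residues$resname, rt$res)]
}

# assemble coordinate gradient from per-heavy-atom dE/d(exposure)
exposureChainGrad <- function(G, at, X, ec, dEde) {
  pr <- ec$pairs
  if (!length(pr$i)) return(G)
  sp <- -ec$sig * (1 - ec$sig) / ec$lambda   # s'(d)
  coefI <- dEde[pr$i] * ec$exposure[pr$i] * (-ec$kappa)
  coefJ <- dEde[pr$j] * ec$exposure[pr$j] * (-ec$kappa)
  coefI[is.na(coefI)] <- 0; coefJ[is.na(coefJ)] <- 0
  addDistGrad(G, pr$i, pr$j, X, (coefI + coefJ) * sp)
}
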