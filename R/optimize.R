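# Gradient-based relaxation over Cartesian coordinates or torsion angles,
# and the chi-rotation mutation operator. Torsion moves are realised as
# rigid rotations of the downstream atom set about the torsion axis, which
# is exactly the forward-kinematics update for the heavy atoms and keeps
# every covalent bond length and angle fixed by construction.

# connected component of `to` in the bond graph with the (from, to) edge
# removed; returns integer atom indices, or NULL if the graph cycles back
# to `from` (torsion locked by a ring or cross-link)
movedComponent <- function(adj, from, to) {
  n <- length(adj)
  seen <- rep(FALSE, n)
  seen[to] <- TRUE
  queue <- to
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (v == to && u == from) next
      if (u == from) return(NULL)
      if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
  }
  which(seen)
}

# enumerate free torsion variables of an annotated structure
torsionVariables <- function(at, include = c("phi", "psi", "omega", "chi")) {
  idx <- at@index
  adj <- idx$adjacency
  nres <- nrow(at@residues)
  vars <- list()
  addVar <- function(name, resi, quad) {
    if (anyNA(quad)) return()
    moved <- movedComponent(adj, quad[2], quad[3])
    if (is.null(moved) || length(moved) == 0L) return()
    vars[[length(vars) + 1L]] <<- list(name = name, resi = resi,
                                       from = quad[2], to = quad[3],
                                       moved = setdiff(moved, quad[3]),
                                       quad = quad)
  }
  for (b in seq_len(nres)) {
    if ("omega" %in% include) addVar("omega", b, idx$omegaIdx[b, ])
    if ("phi" %in% include) addVar("phi", b, idx$phiIdx[b, ])
    if ("chi" %in% include) {
      q <- idx$chiIdx[[b]]
      rot <- idx$chiRotatable[[b]]
      for (k in seq_len(nrow(q)))
        if (isTRUE(rot[k])) addVar(paste0("chi", k), b, q[k, ])
    }
    if ("psi" %in% include) addVar("psi", b, idx$psiIdx[b, ])
  }
  vars
}

# d(total)/d(theta_t) from the Cartesian gradient: rotating the moved set
# by +delta about the axis changes x_a by delta * (k x (x_a - base))
torsionGradient <- function(vars, X, G) {
  vapply(vars, function(v) {
    k <- X[v$to, ] - X[v$from, ]
    k <- k / sqrt(sum(k^2))
    r <- X[v$moved, , drop = FALSE] - matrix(X[v$to, ], length(v$moved), 3,
                                             byrow = TRUE)
    tang <- cbind(k[2] * r[, 3] - k[3] * r[, 2],
                  k[3] * r[, 1] - k[1] * r[, 3],
                  k[1] * r[, 2] - k[2] * r[, 1])
    sum(tang * G[v$moved, , drop = FALSE])
  }, numeric(1))
}

# apply torsion increments in chain order (parents before children)
applyTorsionDeltas <- function(X, vars, delta) {
  for (t in seq_along(vars)) {
    if (delta[t] == 0) next
    v <- vars[[t]]
    k <- X[v$to, ] - X[v$from, ]
    k <- k / sqrt(sum(k^2))
    X[v$moved, ] <- rotateAbout(X[v$moved, , drop = FALSE], X[v$to, ], k,
                                delta[t])
  }
  X
}

checkStartEnergy <- function(ev) {
  if (!all(is.finite(ev$energies))) {
    bad <- rownames(ev$energies)[!apply(is.finite(ev$energies), 1, all)]
    stop("non-finite starting energy in term(s): ",
         paste(bad, collapse = ", "))
  }
}

newAdamState <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0)

adamStep <- function(state, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

finishRelax <- function(s, at, calib, X, traj, termTraj, steps, converged,
                        seed, startBD) {
  coords(s) <- X
  coords(at) <- X
  ev <- evalEnergies(at, calib, grad = FALSE)
  endBD <- methods::new("EnergyBreakdown", energies = ev$energies,
                        total = ev$total, gradient = matrix(0, 0, 3),
                        residues = at@residues)
  methods::new("RelaxResult", trajectory = traj, final = s,
               breakdownStart = startBD, breakdownEnd = endBD,
               stepsTaken = as.integer(steps), converged = converged,
               seed = as.integer(seed), termTrajectory = termTraj)
}

#' Relax a structure by gradient descent over Cartesian coordinates
#'
#' Iteratively updates every atom coordinate along the negative analytic
#' energy gradient. Deterministic given the inputs; convergence is declared
#' when |dE| stays below the tolerance over 10 consecutive steps.
#'
#' @param s a \linkS4class{StructureModel} with hydrogens placed.
#' @param calib a \linkS4class{Calibration}.
#' @param steps maximum number of steps (>= 0).
#' @param stepSize learning rate (Angstrom per unit gradient for plain
#'   gradient descent; Angstrom per step for adaptive moments).
#' @param optimizer \code{"gd"} (plain gradient descent) or \code{"adam"}
#'   (adaptive moment estimation).
#' @param seed integer recorded in the result (relaxation itself is
#'   deterministic; randomness only enters fixture generation).
#' @param tol convergence tolerance on |dE| in kcal/mol.
#' @return a \linkS4class{RelaxResult}.
#' @export
relaxCartesian <- function(s, calib, steps = 100, stepSize = 1e-4,
                           optimizer = c("gd", "adam"), seed = 1L,
                           tol = 1e-4) {
  optimizer <- match.arg(optimizer)
  at <- assignAtomAnnotations(s, calib@params)
  X <- at@coords
  ev <- evalEnergies(at, calib, grad = TRUE)
  checkStartEnergy(ev)
  startBD <- methods::new("EnergyBreakdown", energies = ev$energies,
                          total = ev$total, gradient = ev$gradient,
                          residues = at@residues)
  traj <- ev$total
  termTraj <- matrix(rowSums(ev$energies), 1, 11,
                     dimnames = list(NULL, energyTermNames))
  flat <- 0L
  ad <- newAdamState(length(X))
  k <- 0L
  lr <- stepSize
  while (k < steps) {
    if (optimizer == "adam") {
      ad <- adamStep(ad, as.numeric(ev$gradient), stepSize)
      X2 <- X - matrix(ad$step, nrow(X), 3)
      coords(at) <- X2
      ev2 <- evalEnergies(at, calib, grad = TRUE)
    } else {
      # gradient descent with backtracking step control: the clash
      # exponential makes fixed steps explode on overlapping inputs
      repeat {
        X2 <- X - lr * ev$gradient
        coords(at) <- X2
        ev2 <- evalEnergies(at, calib, grad = TRUE)
        if (is.finite(ev2$total) && ev2$total <= ev$total) break
        lr <- lr / 2
        if (lr < stepSize * 2^-40) break
      }
      lr <- min(lr * 1.5, stepSize)
    }
    X <- X2
    ev <- ev2
    k <- k + 1L
    traj <- c(traj, ev$total)
    termTraj <- rbind(termTraj, rowSums(ev$energies))
    if (!is.finite(ev$total) || ev$total > 1e9) break
    flat <- if (abs(traj[k + 1] - traj[k]) < tol) flat + 1L else 0L
    if (flat >= 10L) break
  }
  finishRelax(s, at, calib, X, traj, termTraj, k, flat >= 10L, seed,
              startBD)
}

#' Relax a structure by gradient descent over torsion angles
#'
#' Optimises phi, psi, omega and rotatable chi torsions; each step maps the
#' Cartesian gradient onto the torsions and applies the updates as rigid
#' rotations of the downstream atoms about the torsion axes, so all
#' covalent bond lengths and angles are preserved exactly. Torsions locked
#' by rings or cross-links (proline, disulfide macrocycles) are held fixed.
#'
#' @inheritParams relaxCartesian
#' @param include character subset of \code{c("phi", "psi", "omega",
#'   "chi")} selecting the optimised torsion families.
#' @return a \linkS4class{RelaxResult}.
#' @export
relaxTorsion <- function(s, calib, steps = 100, stepSize = 1e-4,
                         optimizer = c("gd", "adam"), seed = 1L,
                         tol = 1e-4,
                         include = c("phi", "psi", "omega", "chi")) {
  optimizer <- match.arg(optimizer)
  at <- assignAtomAnnotations(s, calib@params)
  vars <- torsionVariables(at, include)
  X <- at@coords
  ev <- evalEnergies(at, calib, grad = TRUE)
  checkStartEnergy(ev)
  startBD <- methods::new("EnergyBreakdown", energies = ev$energies,
                          total = ev$total, gradient = ev$gradient,
                          residues = at@residues)
  traj <- ev$total
  termTraj <- matrix(rowSums(ev$energies), 1, 11,
                     dimnames = list(NULL, energyTermNames))
  flat <- 0L
  ad <- newAdamState(length(vars))
  k <- 0L
  lr <- stepSize
  while (k < steps && length(vars)) {
    tg <- torsionGradient(vars, X, ev$gradient)
    if (optimizer == "adam") {
      ad <- adamStep(ad, tg, stepSize)
      X2 <- applyTorsionDeltas(X, vars, -ad$step)
      coords(at) <- X2
      ev2 <- evalEnergies(at, calib, grad = TRUE)
    } else {
      repeat {
        X2 <- applyTorsionDeltas(X, vars, -lr * tg)
        coords(at) <- X2
        ev2 <- evalEnergies(at, calib, grad = TRUE)
        if (is.finite(ev2$total) && ev2$total <= ev$total) break
        lr <- lr / 2
        if (lr < stepSize * 2^-40) break
      }
      lr <- min(lr * 1.5, stepSize)
    }
    X <- X2
    ev <- ev2
    k <- k + 1L
    traj <- c(traj, ev$total)
    termTraj <- rbind(termTraj, rowSums(ev$energies))
    if (!is.finite(ev$total) || ev$total > 1e9) break
    flat <- if (abs(traj[k + 1] - traj[k]) < tol) flat + 1L else 0L
    if (flat >= 10L) break
  }
  finishRelax(s, at, calib, X, traj, termTraj, k, flat >= 10L, seed,
              startBD)
}

#' Rotate side-chain chi torsions of one residue
#'
#' Rotates the atoms distal to each chi axis by the requested increments
#' (radians); the backbone and all other residues are untouched. The
#' operation composes: rotating by +delta then -delta restores the input.
#'
#' @param s a \linkS4class{StructureModel}.
#' @param residue residue selector: an integer residue index, or a list
#'   with \code{chain} and \code{resno}.
#' @param delta numeric vector of up to 5 chi increments in radians.
#' @param params parameter list.
#' @return the modified \linkS4class{StructureModel}.
#' @export
rotateChi <- function(s, residue, delta, params = defaultParameters()) {
  at <- assignAtomAnnotations(s, params)
  if (is.list(residue)) {
    b <- which(at@residues$chain == residue$chain &
                 at@residues$resno == residue$resno)
    if (!length(b)) stop("residue selector matches no residue")
    b <- b[1]
  } else {
    b <- as.integer(residue)
    if (is.na(b) || b < 1L || b > nrow(at@residues))
      stop("residue selector matches no residue")
  }
  q <- at@index$chiIdx[[b]]
  valid <- nrow(q) > 0L && !all(is.na(q))
  if (!valid) stop("residue has no valid chi torsions")
  X <- at@coords
  for (k in seq_along(delta)) {
    if (k > nrow(q) || delta[k] == 0 || anyNA(q[k, ])) next
    moved <- movedComponent(at@index$adjacency, q[k, 2], q[k, 3])
    if (is.null(moved)) next # ring-locked
    moved <- setdiff(moved, q[k, 3])
    kv <- X[q[k, 3], ] - X[q[k, 2], ]
    kv <- kv / sqrt(sum(kv^2))
    X[moved, ] <- rotateAbout(X[moved, , drop = FALSE], X[q[k, 3], ], kv,
                              delta[k])
  }
  coords(s) <- X
  s
}
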