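# The total-energy aggregator: runs the eleven energy classes over one
# differentiable pipeline from coordinates to the weighted total.

evalEnergies <- function(at, calib, X = at@coords, grad = TRUE) {
  params <- calib@params
  n <- nrow(X); nres <- nrow(at@residues)
  E <- matrix(0, 11, max(nres, 0),
              dimnames = list(energyTermNames, NULL))
  G <- matrix(0, n, 3)
  if (n == 0L)
    return(list(energies = E, total = 0, gradient = G))
  ec <- exposureCore(at, params)
  el <- termElectrostatics(at, X, params, grad)
  hb <- termHbond(at, X, params, grad)
  ss <- termDisulfide(at, X, params, grad)
  sv <- termSolvationVdw(at, X, params, ec, grad)
  cl <- termClash(at, X, params, calib@clash, grad)
  be <- termBackboneEntropy(at, X, params, calib@densities, grad)
  se <- termSidechainEntropy(at, X, params, ec, el, hb, ss, grad)
  pv <- termPeptideViolation(at, X, params, calib@densities, grad)
  sc <- termSidechainViolation(at, X, params, calib@densities, grad)
  E["hbond", ] <- hb$res
  E["electrostatics", ] <- el$res
  E["disulfide", ] <- ss$res
  E["solvation_polar", ] <- sv$polar
  E["solvation_hydrophobic", ] <- sv$hydrophobic
  E["vdw", ] <- sv$vdw
  E["clash", ] <- cl$res
  E["entropy_backbone", ] <- be$res
  E["entropy_sidechain", ] <- se$res
  E["peptide_violation", ] <- pv$res
  E["sidechain_violation", ] <- sc$res
  if (grad) {
    G <- el$grad + hb$grad + ss$grad + cl$grad + be$grad + se$grad +
      pv$grad + sc$grad
    G <- exposureChainGrad(G, at, X, ec, sv$dEde + se$dEde)
  }
  list(energies = E, total = sum(E), gradient = G)
}

#' Total conformational energy with per-term breakdown
#'
#' Runs all eleven energy classes (hydrogen bonds, screened Coulomb
#' electrostatics, disulfides, polar and hydrophobic solvation, van der
#' Waals burial, clashes, backbone and side-chain entropy, peptide-bond and
#' side-chain conformation violations) over one differentiable pipeline and
#' sums them into the total, in kcal/mol. With \code{gradient = TRUE} the
#' analytic gradient of the total with respect to every atom coordinate is
#' attached.
#'
#' @param s a \linkS4class{StructureModel} with polar hydrogens placed (see
#'   \code{\link{addPolarHydrogens}}).
#' @param calib a \linkS4class{Calibration} (see \code{\link{fitCalibration}}).
#' @param gradient also compute the coordinate gradient.
#' @return an \linkS4class{EnergyBreakdown}.
#' @export
totalEnergy <- function(s, calib, gradient = FALSE) {
  at <- assignAtomAnnotations(s, calib@params)
  ev <- evalEnergies(at, calib, grad = gradient)
  methods::new("EnergyBreakdown", energies = ev$energies, total = ev$total,
               gradient = ev$gradient, residues = at@residues)
}

#' Analytic gradient of the total energy
#'
#' @inheritParams totalEnergy
#' @return numeric N x 3 matrix, kcal/mol per Angstrom, rows aligned with
#'   the atoms of \code{s}.
#' @export
energyGradient <- function(s, calib) {
  totalEnergy(s, calib, gradient = TRUE)@gradient
}

#' Export an energy breakdown as a residue-by-term table
#'
#' @param breakdown an \linkS4class{EnergyBreakdown}.
#' @param path optional TSV output path; when NULL the data.frame is
#'   returned only.
#' @return data.frame (residue rows, term columns plus \code{total}).
#' @export
energyTable <- function(breakdown, path = NULL) {
  df <- cbind(breakdown@residues,
              as.data.frame(t(breakdown@energies)))
  df$total <- colSums(breakdown@energies)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
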