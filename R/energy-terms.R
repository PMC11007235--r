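# Public per-term energy interfaces. Each wraps the internal differentiable
# implementation; energies are in kcal/mol and already carry their class
# weight from the parameter set.

#' Screened Coulomb electrostatic energy
#'
#' E_ij = 332 q_i q_j / (eps d_ij) * exp(-d_ij K), over charged-atom pairs
#' within the cutoff, excluding same-residue and 1-2/1-3 bonded pairs; K is
#' the Debye-Huckel parameter from the configured ionic strength and
#' temperature. Each pair's energy is split half/half between its residues.
#'
#' @param table an \linkS4class{AtomTable}.
#' @param params parameter list.
#' @return list with \code{pairs} (i, j, e) and \code{residue} energies.
#' @export
electrostaticsEnergy <- function(table, params = defaultParameters()) {
  t <- termElectrostatics(table, table@coords, params, grad = FALSE)
  list(pairs = t$pairs[, c("i", "j", "e")], residue = t$res)
}

#' Hydrogen-bond energy
#'
#' A smooth distance well (minimum at 1.9 Angstrom H...acceptor), a cosine
#' power on the donor-H-acceptor angle (optimum linear) and a Gaussian
#' lone-pair factor on the acceptor geometry; each hydrogen is softly
#' assigned to its best acceptor so the selection stays differentiable.
#' Energies are <= 0.
#'
#' @inheritParams electrostaticsEnergy
#' @return list with \code{pairs} (h, dh, a, e) and \code{residue} energies.
#' @export
hydrogenBondEnergy <- function(table, params = defaultParameters()) {
  t <- termHbond(table, table@coords, params, grad = FALSE)
  list(pairs = t$pairs, residue = t$res)
}

#' Disulfide-bond energy
#'
#' SG-SG pairs within 2.5 Angstrom scored by a distance Gaussian (optimum
#' 2.05 Angstrom) modulated by the S-S dihedral geometry (optimum +/- 90
#' degrees); the minimum at ideal geometry is -w_ss.
#'
#' @inheritParams electrostaticsEnergy
#' @return list with \code{pairs} and \code{residue} energies.
#' @export
disulfideEnergy <- function(table, params = defaultParameters()) {
  t <- termDisulfide(table, table@coords, params, grad = FALSE)
  list(pairs = t$pairs, residue = t$res)
}

#' Polar and hydrophobic solvation energies
#'
#' Residue-type transfer-energy coefficients scaled by the residue-level
#' solvent exposure: exposed hydrophilic residues stabilise (negative
#' polar coefficients), exposed hydrophobic residues destabilise (positive
#' hydrophobic coefficients).
#'
#' @inheritParams electrostaticsEnergy
#' @return list with per-residue \code{polar} and \code{hydrophobic}.
#' @export
solvationEnergy <- function(table, params = defaultParameters()) {
  ec <- exposureCore(table, params)
  t <- termSolvationVdw(table, table@coords, params, ec, grad = FALSE)
  list(polar = t$polar, hydrophobic = t$hydrophobic)
}

#' Van der Waals burial energy
#'
#' Per-residue coefficients realised in proportion to atom burial:
#' E(res) = c_vdw(type) * mean over heavy atoms of (1 - exposure);
#' coefficients are negative (stabilising).
#'
#' @inheritParams electrostaticsEnergy
#' @return numeric per-residue energies.
#' @export
vdwEnergy <- function(table, params = defaultParameters()) {
  ec <- exposureCore(table, params)
  termSolvationVdw(table, table@coords, params, ec, grad = FALSE)$vdw
}

#' Steric clash penalty
#'
#' w * exp(10 * (t_g - (d - R_i - R_j))) for pairs whose contact gap
#' d - (R_i + R_j) falls below their group's fitted correction t_g; zero
#' otherwise. Always >= 0.
#'
#' @inheritParams electrostaticsEnergy
#' @param groups a \linkS4class{ClashGroupTable}.
#' @return numeric per-residue energies.
#' @export
clashEnergy <- function(table, groups, params = defaultParameters()) {
  termClash(table, table@coords, params, groups, grad = FALSE)$res
}

#' Backbone entropy
#'
#' w1 * (-ln KDE_o(omega)) + w2 * (-ln KDE_t(phi, psi)) per residue, with
#' masked angles contributing zero.
#'
#' @inheritParams electrostaticsEnergy
#' @param densities a \linkS4class{DensityModel}.
#' @return numeric per-residue energies.
#' @export
backboneEntropy <- function(table, densities,
                            params = defaultParameters()) {
  termBackboneEntropy(table, table@coords, params, densities,
                      grad = FALSE)$res
}

#' Side-chain entropy
#'
#' An amino-acid-specific entropy cost scaled by side-chain burial; when
#' the side chain is locked by hydrogen bonds, strong electrostatics or a
#' disulfide, a smooth gate makes the residue pay the full cost.
#'
#' @inheritParams electrostaticsEnergy
#' @return list with per-residue \code{energy}, the gate activation
#'   \code{gate} and the interaction magnitude \code{interaction}.
#' @export
sidechainEntropy <- function(table, params = defaultParameters()) {
  X <- table@coords
  ec <- exposureCore(table, params)
  el <- termElectrostatics(table, X, params, grad = FALSE)
  hb <- termHbond(table, X, params, grad = FALSE)
  ss <- termDisulfide(table, X, params, grad = FALSE)
  t <- termSidechainEntropy(table, X, params, ec, el, hb, ss, grad = FALSE)
  list(energy = t$res, gate = t$gate, interaction = t$A)
}

#' Peptide-bond violation penalty
#'
#' w * sum over the two peptide angles and the N-Cp bond length of the
#' squared standardised deviation from the fitted Gaussians (the constant
#' normalisation offset is removed so the minimum is exactly zero at the
#' means); chain-break bonds contribute zero.
#'
#' @inheritParams backboneEntropy
#' @return numeric per-residue energies (attributed to the later residue).
#' @export
peptideViolation <- function(table, densities,
                             params = defaultParameters()) {
  termPeptideViolation(table, table@coords, params, densities,
                       grad = FALSE)$res
}

#' Side-chain conformation violation penalty
#'
#' -w_i * ln KDE(chi) under the residue type's fitted chi density, offset
#' by the density's log maximum so the penalty is >= 0; residues without
#' valid chi angles contribute zero.
#'
#' @inheritParams backboneEntropy
#' @return numeric per-residue energies.
#' @export
sidechainViolation <- function(table, densities,
                               params = defaultParameters()) {
  termSidechainViolation(table, table@coords, params, densities,
                         grad = FALSE)$res
}
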