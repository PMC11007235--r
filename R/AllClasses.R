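#' @import methods
NULL

#' Hierarchical protein structure model
#'
#' A chain/residue/atom representation of a protein structure. Atoms are held
#' in a flat data frame (one row per atom) ordered by chain, residue and
#' topological atom order; coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{icode}, \code{resname}, \code{atom}, \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{occ}, \code{altloc}.
#' @slot provenance character, source file name or generator description.
#' @exportClass StructureModel
setClass("StructureModel",
         representation(atoms = "data.frame", provenance = "character"),
         prototype(atoms = data.frame(), provenance = NA_character_))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "occ", "altloc")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0L) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("coordinates must be finite")
    # residue order strictly increasing by (resno, icode) within a chain
    for (ch in unique(a$chain)) {
      r <- a[a$chain == ch, c("resno", "icode")]
      key <- paste(r$resno, r$icode)
      runs <- rle(key)$values
      num <- as.numeric(sub(" .*", "", runs))
      ico <- sub(".* ", "", runs)
      ord <- order(num, ico)
      if (any(duplicated(runs)) || !all(ord == seq_along(runs)))
        return(sprintf("residues of chain %s are not strictly increasing", ch))
    }
  }
  TRUE
})

#' Flat tensorised atom view
#'
#' Per-atom physical annotations aligned with an N x 3 coordinate matrix:
#' partial charges (elementary charge units), van der Waals radii (Angstrom),
#' donor/acceptor/sulfur/backbone flags, residue and chain maps back into the
#' originating \linkS4class{StructureModel}, plus precomputed index tables
#' (covalent bonds, torsion quadruples) used by the energy terms.
#'
#' @slot coords numeric N x 3 matrix, Angstrom.
#' @slot charge numeric, per-atom partial charge, |q| <= 1.
#' @slot radius numeric, per-atom radius, strictly positive.
#' @slot isDonorH,isAcceptor,isSulfur,isBackbone logical flags.
#' @slot residueIndex,chainIndex integer maps to residues/chains.
#' @slot element,atomName,resname character annotations.
#' @slot donorHeavy integer; for each donor hydrogen the index of its heavy
#'   donor atom, NA elsewhere.
#' @slot acceptorAntecedent integer; for each acceptor the index of its bonded
#'   heavy neighbour (lone-pair direction reference), NA elsewhere.
#' @slot residues data.frame, one row per residue (chain, resno, icode,
#'   resname).
#' @slot index list of precomputed index tables (bonds, bonded12/13 keys,
#'   torsion quadruples, side-chain membership, disulfide pairs).
#' @exportClass AtomTable
setClass("AtomTable",
         representation(coords = "matrix", charge = "numeric",
                        radius = "numeric", isDonorH = "logical",
                        isAcceptor = "logical", isSulfur = "logical",
                        isBackbone = "logical", residueIndex = "integer",
                        chainIndex = "integer", element = "character",
                        atomName = "character", resname = "character",
                        donorHeavy = "integer",
                        acceptorAntecedent = "integer",
                        residues = "data.frame", index = "list"))

setValidity("AtomTable", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must be N x 3")
  lens <- c(length(object@charge), length(object@radius),
            length(object@isDonorH), length(object@isAcceptor),
            length(object@isSulfur), length(object@isBackbone),
            length(object@residueIndex), length(object@element))
  if (!all(lens == n)) return("annotation vectors must match coords rows")
  if (n > 0L) {
    if (any(object@radius <= 0)) return("radii must be strictly positive")
    if (any(abs(object@charge) > 1 + 1e-9)) return("|charge| must be <= 1")
    if (any(object@isDonorH & object@element != "H"))
      return("donor hydrogens must have element H")
    if (any(diff(object@residueIndex) < 0L))
      return("residueIndex must be non-decreasing")
  }
  TRUE
})

#' Per-residue backbone and side-chain torsion angles
#'
#' Angles are in radians wrapped to (-pi, pi]; NA encodes an invalid slot
#' (chain terminus or missing defining atoms). \code{chi} has five columns;
#' glycine and alanine rows are all-NA by construction.
#'
#' @slot phi,psi,omega numeric per-residue angles, NA where undefined.
#' @slot chi numeric n x 5 matrix of side-chain torsions.
#' @slot residueType character per-residue three-letter code.
#' @slot index list of atom-index quadruples defining each angle.
#' @exportClass TorsionSet
setClass("TorsionSet",
         representation(phi = "numeric", psi = "numeric", omega = "numeric",
                        chi = "matrix", residueType = "character",
                        index = "list"))

setValidity("TorsionSet", function(object) {
  n <- length(object@phi)
  if (length(object@psi) != n || length(object@omega) != n ||
      nrow(object@chi) != n || length(object@residueType) != n)
    return("per-residue slots must have equal length")
  if (ncol(object@chi) != 5L) return("chi must have 5 columns")
  ang <- c(object@phi, object@psi, object@omega, object@chi)
  ang <- ang[!is.na(ang)]
  if (length(ang) && (any(ang <= -pi - 1e-9) || any(ang > pi + 1e-9)))
    return("angles must lie in (-pi, pi]")
  TRUE
})

#' Fitted clash-group distance corrections
#'
#' Ten-percent order-statistic corrections t_g of the observed contact gap
#' d - (R_i + R_j), one for each of the six contact groups.
#'
#' @slot correction named numeric of length 6 (Angstrom).
#' @slot counts named integer, samples per group.
#' @exportClass ClashGroupTable
setClass("ClashGroupTable",
         representation(correction = "numeric", counts = "integer"))

clashGroupNames <- c("same_residue", "hbond", "disulfide",
                     "consecutive_backbone", "donor_acceptor", "other")

setValidity("ClashGroupTable", function(object) {
  if (length(object@correction) != 6L || length(object@counts) != 6L)
    return("exactly six clash groups are required")
  if (!identical(names(object@correction), clashGroupNames))
    return(paste("groups must be named:",
                 paste(clashGroupNames, collapse = ", ")))
  TRUE
})

#' Fitted periodic densities and peptide-geometry Gaussians
#'
#' Houses the periodic kernel mixtures for backbone (phi, psi) per residue
#' type, the omega density, the per-type chi densities, and the three
#' peptide-geometry Gaussians (two bond angles and the N-C bond length).
#'
#' @slot backbone named list (per residue type) of von Mises product-kernel
#'   mixtures: \code{centers} (m x 2) and \code{kappa} (length 2).
#' @slot omega a single 1-D mixture: \code{centers} (m x 1), \code{kappa}.
#' @slot chi named list per residue type, dimension = number of chi slots.
#' @slot peptide data.frame with columns \code{name}, \code{mean}, \code{sd}
#'   for angle_CA_N_Cp (rad), angle_CAp_Cp_N (rad), dist_N_Cp (Angstrom).
#' @slot floor numeric density floor applied before taking logs.
#' @exportClass DensityModel
setClass("DensityModel",
         representation(backbone = "list", omega = "list", chi = "list",
                        peptide = "data.frame", floor = "numeric"),
         prototype(floor = 1e-12))

#' Calibration bundle
#'
#' Everything \code{\link{totalEnergy}} needs besides the structure: the
#' parameter set, the clash-group corrections and the fitted densities.
#'
#' @slot params list, see \code{\link{defaultParameters}}.
#' @slot clash \linkS4class{ClashGroupTable}.
#' @slot densities \linkS4class{DensityModel}.
#' @exportClass Calibration
setClass("Calibration",
         representation(params = "list", clash = "ClashGroupTable",
                        densities = "DensityModel"))

#' Per-term, per-residue energy breakdown
#'
#' @slot energies numeric 11 x n matrix (term x residue), kcal/mol, rows
#'   already multiplied by their class weights.
#' @slot total numeric scalar, kcal/mol.
#' @slot gradient numeric N x 3 matrix of d(total)/d(coordinates), or a
#'   0 x 3 matrix when gradients were not requested.
#' @slot residues data.frame describing the residue columns.
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
         representation(energies = "matrix", total = "numeric",
                        gradient = "matrix", residues = "data.frame"))

energyTermNames <- c("hbond", "electrostatics", "disulfide",
                     "solvation_polar", "solvation_hydrophobic", "vdw",
                     "clash", "entropy_backbone", "entropy_sidechain",
                     "peptide_violation", "sidechain_violation")

setValidity("EnergyBreakdown", function(object) {
  e <- object@energies
  if (nrow(e) != 11L || !identical(rownames(e), energyTermNames))
    return("energies must have the 11 canonical term rows")
  if (!all(is.finite(e))) return("all energies must be finite")
  if (abs(object@total - sum(e)) >
      1e-6 * max(1, abs(object@total)))
    return("total must equal the sum of all term entries")
  nonneg <- c("clash", "peptide_violation", "sidechain_violation")
  if (any(e[nonneg, ] < -1e-9))
    return("clash and violation terms must be >= 0")
  TRUE
})

#' Result of a gradient-based relaxation
#'
#' @slot trajectory numeric, total energy per step (length stepsTaken + 1).
#' @slot final \linkS4class{StructureModel} after the last step.
#' @slot breakdownStart,breakdownEnd \linkS4class{EnergyBreakdown}.
#' @slot stepsTaken integer.
#' @slot converged logical.
#' @slot seed integer.
#' @slot termTrajectory numeric (stepsTaken + 1) x 11 matrix of per-term
#'   totals along the trajectory.
#' @exportClass RelaxResult
setClass("RelaxResult",
         representation(trajectory = "numeric", final = "StructureModel",
                        breakdownStart = "EnergyBreakdown",
                        breakdownEnd = "EnergyBreakdown",
                        stepsTaken = "integer", converged = "logical",
                        seed = "integer", termTrajectory = "matrix"))

setValidity("RelaxResult", function(object) {
  if (length(object@trajectory) != object@stepsTaken + 1L)
    return("trajectory length must be stepsTaken + 1")
  TRUE
})
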