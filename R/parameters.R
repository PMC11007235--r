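# Parameter handling: the YAML parameter file, per-residue coefficient
# tables, atom annotation tables and the internal-coordinate topology
# template shipped under extdata. All tables are config-overridable: any
# file path in the parameter list replaces the shipped default.

fgExtdata <- function(file) {
  p <- system.file("extdata", file, package = "foldgrad")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file) # during dev
  if (!file.exists(p)) stop("cannot locate shipped data file: ", file)
  p
}

readTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
}

# Offset (degrees) of the fixed improper-like torsion dihedral(CB, CA, N, C)
# that selects the L enantiomer; see the methods vignette.
CB_CHIRAL_OFFSET <- -122.6

#' Default parameter set
#'
#' Returns the shipped defaults: physical conditions (T = 298 K, I = 0.05 M,
#' dielectric 80), per-term weights (all 1.0), exposure, hydrogen-bond,
#' disulfide, clash and density settings, per-element radii, and the
#' per-residue and per-atom coefficient tables. Every entry can be
#' overridden via \code{readParameterFile} or by editing the returned list.
#'
#' @param file optional YAML parameter file overriding the shipped defaults.
#' @return a named list; tables are attached under \code{$tables}.
#' @export
defaultParameters <- function(file = NULL) {
  params <- yaml::read_yaml(fgExtdata("default_params.yaml"))
  if (!is.null(file)) {
    override <- yaml::read_yaml(file)
    params <- utils::modifyList(params, override)
  }
  params$tables <- list(
    topology = readTSV(params$topology_file %||% fgExtdata("topology.tsv")),
    chi = readTSV(params$chi_file %||% fgExtdata("chi_atoms.tsv")),
    atoms = readTSV(params$atom_params_file %||%
                      fgExtdata("atom_params.tsv")),
    hydrogens = readTSV(params$hydrogens_file %||%
                          fgExtdata("hydrogens.tsv")),
    residues = readTSV(params$residue_params_file %||%
                         fgExtdata("residue_params.tsv")),
    rigid = readTSV(params$rigid_groups_file %||%
                      fgExtdata("rigid_groups.tsv")))
  params
}

#' Read a parameter file
#'
#' A YAML key-value file whose entries override the shipped defaults
#' (missing keys keep their default values).
#'
#' @param path YAML file path.
#' @return parameter list as in \code{\link{defaultParameters}}.
#' @export
readParameterFile <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  defaultParameters(file = path)
}

#' Write a parameter list to a YAML file
#'
#' @param params parameter list.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeParameterFile <- function(params, path) {
  params$tables <- NULL
  yaml::write_yaml(params, path)
  invisible(path)
}

aminoAcids3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                 Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                 L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                 S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

backboneAtoms <- c("N", "CA", "C", "O", "OXT")

# element from a PDB atom name within standard amino acids
elementFromName <- function(atomName) {
  e <- substr(gsub("^[0-9]", "", atomName), 1, 1)
  ifelse(e %in% c("C", "N", "O", "S", "H"), e, "X")
}

# topology rows applying to a residue type: backbone rows ('*', minus CB for
# GLY) followed by the type-specific side-chain rows
topologyFor <- function(topology, resname) {
  bb <- topology[topology$res == "*", , drop = FALSE]
  if (resname == "GLY") bb <- bb[bb$atom != "CB", , drop = FALSE]
  sc <- topology[topology$res == resname, , drop = FALSE]
  out <- rbind(bb, sc)
  out$offsetNum <- ifelse(out$offset == "CHIRAL", CB_CHIRAL_OFFSET,
                          suppressWarnings(as.numeric(out$offset)))
  out
}
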