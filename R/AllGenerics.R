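#' Atom coordinates of a structure-like object
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{AtomTable}.
#' @return numeric N x 3 matrix in Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @param value numeric N x 3 matrix.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Number of atoms
#' @param x a structure-like object.
#' @return integer.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Residue table of a structure-like object
#' @param x a structure-like object.
#' @return data.frame with one row per residue (chain, resno, icode, resname).
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname coords
setMethod("coords", "StructureModel", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @rdname coords
setMethod("coords<-", "StructureModel", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms),
            ncol(value) == 3L)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
})

#' @rdname coords
setMethod("coords", "AtomTable", function(x) x@coords)

#' @rdname coords
setMethod("coords<-", "AtomTable", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@coords),
            ncol(value) == 3L)
  x@coords <- value
  x
})

#' @rdname nAtoms
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @rdname nAtoms
setMethod("nAtoms", "AtomTable", function(x) nrow(x@coords))

#' @rdname residues
setMethod("residues", "StructureModel", function(x) {
  a <- x@atoms
  if (nrow(a) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      icode = character(), resname = character()))
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resname = a$resname[first],
             stringsAsFactors = FALSE)
})

#' @rdname residues
setMethod("residues", "AtomTable", function(x) x@residues)

#' Per-atom residue index of a StructureModel
#' @param x a \linkS4class{StructureModel}.
#' @return integer vector mapping each atom to its residue row.
#' @export
residueIndex <- function(x) {
  if (is(x, "AtomTable")) return(x@residueIndex)
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  cumsum(!duplicated(key))[match(key, key)] # stable: first occurrence order
}

setMethod("show", "StructureModel", function(object) {
  r <- residues(object)
  cat(sprintf("StructureModel: %d atom(s), %d residue(s), %d chain(s)\n",
              nAtoms(object), nrow(r), length(unique(r$chain))))
  if (!is.na(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "AtomTable", function(object) {
  cat(sprintf(paste0("AtomTable: %d atom(s) (%d donor H, %d acceptor, ",
                     "%d sulfur)\n"),
              nAtoms(object), sum(object@isDonorH), sum(object@isAcceptor),
              sum(object@isSulfur)))
})

setMethod("show", "TorsionSet", function(object) {
  cat(sprintf("TorsionSet: %d residue(s); valid phi %d, psi %d, omega %d, chi slots %d\n",
              length(object@phi), sum(!is.na(object@phi)),
              sum(!is.na(object@psi)), sum(!is.na(object@omega)),
              sum(!is.na(object@chi))))
})

setMethod("show", "ClashGroupTable", function(object) {
  cat("ClashGroupTable (t_g = 10th percentile of d - (Ri+Rj), Angstrom):\n")
  for (g in names(object@correction))
    cat(sprintf("  %-22s %8.4f  (n = %d)\n", g, object@correction[[g]],
                object@counts[[g]]))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown: %d residue(s), total = %.4f kcal/mol\n",
              ncol(object@energies), object@total))
  s <- rowSums(object@energies)
  for (t in rownames(object@energies))
    cat(sprintf("  %-22s %10.4f\n", t, s[[t]]))
})

setMethod("show", "RelaxResult", function(object) {
  cat(sprintf(paste0("RelaxResult: %d step(s), E %.4f -> %.4f kcal/mol, ",
                     "converged: %s\n"),
              object@stepsTaken, object@trajectory[1],
              object@trajectory[length(object@trajectory)],
              object@converged))
})

setMethod("show", "DensityModel", function(object) {
  cat(sprintf(paste0("DensityModel: backbone densities for %d type(s), ",
                     "chi densities for %d type(s), omega: %s, peptide ",
                     "Gaussians: %d\n"),
              length(object@backbone), length(object@chi),
              if (length(object@omega)) "fitted" else "absent",
              nrow(object@peptide)))
})

setMethod("show", "Calibration", function(object) {
  cat("Calibration bundle\n")
  show(object@clash)
  show(object@densities)
})
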