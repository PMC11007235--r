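# PDB input/output, polar hydrogen placement and per-atom physical
# annotation. Parsing and writing of the fixed-column PDB records goes
# through bio3d; model selection, alternate-location resolution and water
# removal are applied on top.

newStructureModel <- function(atoms, provenance = NA_character_) {
  rownames(atoms) <- NULL
  methods::new("StructureModel", atoms = atoms, provenance = provenance)
}

emptyAtoms <- function() {
  data.frame(chain = character(), resno = integer(), icode = character(),
             resname = character(), atom = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
             altloc = character(), stringsAsFactors = FALSE)
}

waterNames <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB file into a StructureModel
#'
#' Parses ATOM/HETATM records of the first MODEL block, resolves alternate
#' locations to the highest-occupancy conformer, and drops waters. HETATM
#' records other than water are ignored unless \code{keepHetatm}.
#'
#' @param path PDB file path.
#' @param keepHetatm keep non-water HETATM records (default FALSE).
#' @return a \linkS4class{StructureModel}.
#' @export
readPDB <- function(path, keepHetatm = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  if (!any(startsWith(lines, "ATOM")))
    stop("no ATOM records found in ", path)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  if (!keepHetatm) a <- a[a$type == "ATOM" | a$resid %in% waterNames, ]
  a <- a[!(a$resid %in% waterNames), ]
  if (nrow(a) == 0L) stop("no usable ATOM records in ", path)
  if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
    stop("non-finite coordinates in ", path)
  # alternate locations: keep the highest-occupancy altloc per atom site
  alt <- a$alt; alt[is.na(alt)] <- ""
  occ <- a$o; occ[is.na(occ)] <- 1
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  a <- a[keep, ]
  chain <- a$chain; chain[is.na(chain)] <- "A"
  icode <- a$insert; icode[is.na(icode)] <- ""
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- elementFromName(a$elety[miss])
  elem <- trimws(elem)
  atoms <- data.frame(chain = chain, resno = as.integer(a$resno),
                      icode = icode, resname = a$resid, atom = a$elety,
                      element = elem, x = a$x, y = a$y, z = a$z,
                      occ = occ[keep],
                      altloc = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
  newStructureModel(atoms, provenance = basename(path))
}

#' Write a StructureModel to a PDB file
#'
#' @param s a \linkS4class{StructureModel}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(s, path) {
  a <- s@atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
    a[, c("x", "y", "z")]))), type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$atom, chain = a$chain, insert = ifelse(nzchar(a$icode),
                                                     a$icode, ""),
    o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# split atom data.frame into per-residue row index list (in order)
residueBlocks <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  idx <- cumsum(!duplicated(key))
  split(seq_len(nrow(atoms)), idx)
}

findAtom <- function(atoms, rows, name) {
  hit <- rows[atoms$atom[rows] == name]
  if (length(hit)) hit[1] else NA_integer_
}

#' Place polar hydrogens by ideal geometry
#'
#' Adds the backbone amide hydrogen (bond length 1.01 Angstrom, in the plane
#' of C(prev)-N-CA opposite the bisector; none for proline or chain-initial
#' residues) and the side-chain polar hydrogens (Ser/Thr/Tyr hydroxyls,
#' Lys NZ, Arg NE/NH, Asn/Gln amides, His ring NH, Trp NE1, Cys SH when the
#' cysteine is not disulfide-bonded). Existing hydrogens are preserved, so
#' the operation is idempotent. Hydrogens whose parent heavy atoms are
#' missing are skipped with a warning.
#'
#' @param s a \linkS4class{StructureModel}.
#' @param params parameter list (see \code{\link{defaultParameters}}).
#' @return a \linkS4class{StructureModel} including the polar hydrogens.
#' @export
addPolarHydrogens <- function(s, params = defaultParameters()) {
  a <- s@atoms
  if (nrow(a) == 0L) return(s)
  blocks <- residueBlocks(a)
  htab <- params$tables$hydrogens
  ssCut <- params$disulfide$cutoff %||% 2.5
  # SG atoms engaged in a disulfide (suppress their thiol H)
  sgIdx <- which(a$atom == "SG" & a$resname == "CYS")
  ssBound <- rep(FALSE, nrow(a))
  if (length(sgIdx) > 1L) {
    X <- as.matrix(a[sgIdx, c("x", "y", "z")])
    D <- as.matrix(stats::dist(X))
    hit <- which(D > 0 & D <= ssCut, arr.ind = TRUE)
    ssBound[sgIdx[unique(hit[, 1])]] <- TRUE
  }
  skipped <- character()
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    res <- a[rows, , drop = FALSE]
    resname <- res$resname[1]
    newH <- list()
    place1 <- function(hname, p1, p2, p3, bond, angleDeg, torsDeg) {
      if (hname %in% res$atom) return(NULL) # already present
      i1 <- findAtom(a, rows, p1); i2 <- findAtom(a, rows, p2)
      i3 <- findAtom(a, rows, p3)
      if (anyNA(c(i1, i2, i3))) {
        skipped <<- c(skipped, paste0(resname, res$resno[1], ":", hname))
        return(NULL)
      }
      xyz <- nerfPlace(as.numeric(a[i3, c("x", "y", "z")]),
                       as.numeric(a[i2, c("x", "y", "z")]),
                       as.numeric(a[i1, c("x", "y", "z")]),
                       bond, deg2rad(angleDeg), deg2rad(torsDeg))
      data.frame(chain = res$chain[1], resno = res$resno[1],
                 icode = res$icode[1], resname = resname, atom = hname,
                 element = "H", x = xyz[1], y = xyz[2], z = xyz[3],
                 occ = 1, altloc = "", stringsAsFactors = FALSE)
    }
    # backbone amide hydrogen
    if (resname != "PRO" && !("H" %in% res$atom) && b > 1L) {
      prev <- blocks[[b - 1L]]
      sameChain <- a$chain[prev[1]] == res$chain[1]
      iN <- findAtom(a, rows, "N"); iCA <- findAtom(a, rows, "CA")
      iCp <- findAtom(a, prev, "C")
      if (sameChain && !anyNA(c(iN, iCA, iCp))) {
        N <- as.numeric(a[iN, c("x", "y", "z")])
        CA <- as.numeric(a[iCA, c("x", "y", "z")])
        Cp <- as.numeric(a[iCp, c("x", "y", "z")])
        if (sqrt(sum((N - Cp)^2)) < 2.0) { # genuine peptide bond
          u1 <- (Cp - N) / sqrt(sum((Cp - N)^2))
          u2 <- (CA - N) / sqrt(sum((CA - N)^2))
          bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
          h <- N - 1.01 * bis
          newH$H <- data.frame(chain = res$chain[1], resno = res$resno[1],
                               icode = res$icode[1], resname = resname,
                               atom = "H", element = "H", x = h[1],
                               y = h[2], z = h[3], occ = 1, altloc = "",
                               stringsAsFactors = FALSE)
        }
      }
    }
    hr <- htab[htab$res == resname, , drop = FALSE]
    for (k in seq_len(nrow(hr))) {
      if (resname == "CYS" && hr$hname[k] == "HG") {
        iSG <- findAtom(a, rows, "SG")
        if (!is.na(iSG) && ssBound[iSG]) next
      }
      h <- place1(hr$hname[k], hr$parent[k], hr$p2[k], hr$p3[k],
                  hr$bond[k], hr$angle[k], hr$tors[k])
      if (!is.null(h)) newH[[hr$hname[k]]] <- h
    }
    out[[b]] <- do.call(rbind, c(list(res), unname(newH)))
  }
  if (length(skipped))
    warning("skipped hydrogens (missing parent heavy atoms): ",
            paste(skipped, collapse = ", "))
  newStructureModel(do.call(rbind, out), provenance = s@provenance)
}
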