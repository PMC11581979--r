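#' Read a protein structure for shell analysis
#'
#' Thin wrapper around \code{bio3d::read.pdb} that keeps the first model
#' only and resolves alternate locations by highest occupancy. Hydrogens
#' are retained; distance queries drop them by default.
#'
#' @param path PDB file path.
#' @return a \code{bio3d} pdb object with de-duplicated alternate locations.
#' @export
readStructure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$resid, a$elety)
    keep <- rep(TRUE, nrow(a))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      occ <- a$o[idx]
      occ[is.na(occ)] <- 1
      keep[idx] <- seq_along(idx) == which.max(occ)
    }
    pdb$atom <- a[keep, , drop = FALSE]
  }
  pdb
}

#' Protein residues within a distance shell of a bound ligand
#'
#' Returns the residue positions having any atom within \code{radius}
#' angstroms (all-atom minimum Euclidean distance) of any atom of the named
#' ligand. Heavy atoms only by default, since hydrogens are rarely present
#' in X-ray structures.
#'
#' @param structure a pdb object from \code{\link{readStructure}}.
#' @param ligandId residue name of the ligand (HETATM resid).
#' @param radius shell radius in angstroms, default 6.
#' @param heavyOnly drop hydrogen atoms before measuring (default TRUE).
#' @return sorted integer vector of residue numbers.
#' @export
residuesNearLigand <- function(structure, ligandId, radius = 6.0,
                               heavyOnly = TRUE) {
  if (radius < 0) stop("radius must be >= 0")
  a <- structure$atom
  lig <- a$type == "HETATM" & a$resid == ligandId
  if (!any(lig)) {
    avail <- sort(unique(a$resid[a$type == "HETATM"]))
    stop("ligand '", ligandId, "' not found; available ligand names: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  prot <- a$type == "ATOM"
  if (heavyOnly) {
    elem <- if ("elesy" %in% names(a)) trimws(a$elesy) else rep("", nrow(a))
    isH <- elem %in% c("H", "D")
    # fall back to the atom-name convention where the element column is blank
    blank <- !nzchar(elem) | is.na(elem)
    isH[blank] <- grepl("^[0-9]*H", trimws(a$elety[blank]))
    prot <- prot & !isH
    lig <- lig & !isH
  }
  if (!any(lig) || !any(prot)) return(integer())
  px <- as.matrix(a[prot, c("x", "y", "z")])
  lx <- as.matrix(a[lig, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rep(1, nrow(lx))) +
    outer(rep(1, nrow(px)), rowSums(lx^2)) - 2 * px %*% t(lx)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  sort(unique(a$resno[prot][mind < radius]))
}

#' Read a one-position-per-line sites file
#'
#' @param path text file with one 1-based integer residue position per line.
#' @return integer vector of positions.
#' @export
readSites <- function(path) {
  x <- readLines(path)
  x <- trimws(x[nzchar(trimws(x))])
  as.integer(x)
}
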