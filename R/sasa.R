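# van der Waals radii (Angstrom), Bondi-style values as commonly used for
# protein heavy atoms; SE covers selenomethionine.
.vdwRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20)

# Theoretical maximum residue SASA (Angstrom^2) in an extended Gly-X-Gly
# context (Tien et al. 2013, theoretical column); denominators for
# relative SASA.
.maxResidueSasa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Aliphatic/aromatic side chains with positive Kyte-Doolittle hydropathy;
# the set scanned for exposed aggregation-prone residues.
.hydrophobicSet <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "CYS")

# Quasi-uniform points on the unit sphere (Fibonacci / golden-spiral
# lattice); deterministic for a given n.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over every heavy atom: for each atom, a
#' quasi-uniform lattice of \code{nPoints} test points is placed on the
#' expanded sphere of radius \eqn{r_{atom} + probe}; the accessible fraction
#' is the share of points falling inside no other atom's expanded sphere,
#' and the atom's SASA is that fraction times \eqn{4\pi(r_{atom}+probe)^2}.
#' Residue SASA sums the residue's atoms; relative SASA divides by a
#' residue-type theoretical maximum. Hydrogens are ignored. Used here to ask
#' whether truncation exposes the aggregation-prone segment ILTIITL
#' (residues 251-257) of the p53 core domain.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param probe probe radius in Angstrom, default 1.4 (water).
#' @param nPoints sphere points per atom, default 960.
#' @return a \linkS4class{SasaProfile}.
#' @examples
#' s <- genToyStructure(8, seed = 1)
#' computeSasa(s)
#' @export
computeSasa <- function(s, probe = 1.4, nPoints = 960L) {
  stopifnot(is(s, "ProteinStructure"))
  if (probe < 0) stop("probe radius must be non-negative")
  nPoints <- as.integer(nPoints)
  if (nPoints < 1L) stop("nPoints must be positive")
  a <- s@atoms[s@atoms$element != "H", , drop = FALSE]
  radii <- .vdwRadii[a$element]
  if (anyNA(radii)) {
    bad <- unique(paste0(a$elety[is.na(radii)], " (element ",
                         a$element[is.na(radii)], ")"))
    stop("no van der Waals radius for atom(s): ",
         paste(bad, collapse = ", "))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rExp <- radii + probe
  n <- nrow(xyz)
  sphere <- .spherePoints(nPoints)
  atomSasa <- numeric(n)
  # neighbour lists from one pairwise distance pass
  dmat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < rExp[i] + rExp & seq_len(n) != i)
    if (!length(nb)) {
      atomSasa[i] <- 4 * pi * rExp[i]^2
      next
    }
    pts <- sweep(sphere * rExp[i], 2, xyz[i, ], `+`)
    buried <- rep(FALSE, nPoints)
    for (j in nb) {
      free <- which(!buried)
      if (!length(free)) break
      d2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      buried[free[d2 < rExp[j]^2]] <- TRUE
    }
    atomSasa[i] <- mean(!buried) * 4 * pi * rExp[i]^2
  }
  resSasa <- tapply(atomSasa, a$resno, sum)
  resno <- as.integer(names(resSasa))
  resid <- a$resid[match(resno, a$resno)]
  maxS <- .maxResidueSasa[resid]
  if (anyNA(maxS))
    warning("no maximum-SASA reference for residue type(s): ",
            paste(unique(resid[is.na(maxS)]), collapse = ", "),
            "; relative SASA set to NA")
  df <- data.frame(resno = resno, resid = resid,
                   sasa = as.numeric(resSasa),
                   relSasa = as.numeric(resSasa) / as.numeric(maxS),
                   row.names = NULL)
  df <- df[order(df$resno), , drop = FALSE]
  new("SasaProfile", residues = df, probeRadius = probe,
      nPoints = nPoints)
}

#' Exposed hydrophobic residues in a segment
#'
#' Residues within \code{segment} whose type belongs to the hydrophobic set
#' (Ala, Val, Leu, Ile, Met, Phe, Cys) and whose relative SASA meets the
#' exposure threshold. Applied to the aggregation region ILTIITL (residues
#' 251-257), this flags the solvent-facing Leu/Ile residues whose exposure
#' drives p53 aggregation.
#'
#' @param p a \linkS4class{SasaProfile}.
#' @param segment inclusive residue range \code{c(first, last)}.
#' @param relThreshold minimum relative SASA to call a residue exposed,
#'   default 0.25.
#' @return data.frame of the qualifying residues (\code{resno},
#'   \code{resid}, \code{sasa}, \code{relSasa}), possibly empty.
#' @export
exposedHydrophobics <- function(p, segment, relThreshold = 0.25) {
  stopifnot(is(p, "SasaProfile"))
  segment <- .checkRange(segment)
  r <- p@residues
  inSeg <- r$resno >= segment[1] & r$resno <= segment[2]
  if (!any(inSeg))
    stop("segment ", segment[1], "-", segment[2],
         " lies outside the profiled residues (",
         min(r$resno), "-", max(r$resno), ")")
  sel <- inSeg & r$resid %in% .hydrophobicSet &
    !is.na(r$relSasa) & r$relSasa >= relThreshold
  r[sel, , drop = FALSE]
}

#' Reference tables used by the SASA module
#'
#' @return list with the van der Waals radius table (\code{vdwRadii},
#'   Angstrom), the residue-type maximum SASA table
#'   (\code{maxResidueSasa}, Angstrom^2) and the hydrophobic residue set
#'   (\code{hydrophobicSet}).
#' @export
sasaReferenceTables <- function() {
  list(vdwRadii = .vdwRadii, maxResidueSasa = .maxResidueSasa,
       hydrophobicSet = .hydrophobicSet)
}
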