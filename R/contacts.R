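#' Compute a C-alpha contact map
#'
#' All unordered residue pairs whose C-alpha atoms are within \code{cutoff}
#' Angstrom (inclusive) and at least \code{minSeparation} apart in sequence.
#' The 8 A C-alpha rule is the standard tertiary-contact definition for the
#' p53 core domain; the separation filter keeps the trivial near-diagonal
#' (i, i+1) off the map.
#'
#' @param s a \linkS4class{ProteinStructure}; residues without a C-alpha are
#'   skipped with a warning.
#' @param cutoff contact distance in Angstrom (> 0), default 8.
#' @param minSeparation minimum |i - j|, default 2.
#' @return a \linkS4class{ContactMap}.
#' @examples
#' s <- genToyStructure(25, seed = 1)
#' computeContactMap(s)
#' @export
computeContactMap <- function(s, cutoff = 8.0, minSeparation = 2L) {
  stopifnot(is(s, "ProteinStructure"))
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be a single positive distance in Angstrom")
  minSeparation <- as.integer(minSeparation)
  ca <- .caCoords(s)
  miss <- attr(ca, "missing")
  if (length(miss))
    warning("residues without a C-alpha skipped: ",
            paste(miss, collapse = ", "))
  resno <- as.integer(rownames(ca))
  n <- nrow(ca)
  pairs <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (n >= 2L) {
    d <- as.matrix(stats::dist(ca))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    ri <- resno[idx[, 1]]
    rj <- resno[idx[, 2]]
    dd <- d[idx]
    keep <- dd <= cutoff & abs(ri - rj) >= minSeparation
    if (any(keep)) {
      i <- pmin(ri[keep], rj[keep])
      j <- pmax(ri[keep], rj[keep])
      ord <- order(i, j)
      pairs <- data.frame(i = i[ord], j = j[ord],
                          distance = dd[keep][ord], row.names = NULL)
    }
  }
  new("ContactMap", pairs = pairs, cutoff = cutoff,
      minSeparation = minSeparation)
}

#' Partition contacts by the effect of an N-terminal truncation
#'
#' Classifies every contact of a full-length map by what a truncation
#' starting at \code{firstRetained} does to it: \code{lost} pairs have
#' exactly one member deleted (a retained residue loses its partner — the
#' structurally informative class, e.g. the N-to-C contacts within the LSH
#' motif that Delta133/Delta160 disrupt), \code{removed} pairs have both
#' members deleted, and \code{retained} pairs survive intact. The three
#' classes partition the map exactly.
#'
#' @param m a \linkS4class{ContactMap} computed on the untruncated
#'   structure.
#' @param firstRetained first residue number kept by the truncation.
#' @return list with data.frames \code{lost}, \code{removed},
#'   \code{retained} (columns \code{i}, \code{j}, \code{distance}).
#' @examples
#' s <- genToyStructure(40, seed = 1)
#' m <- computeContactMap(s)
#' str(lostInterregionContacts(m, 15))
#' @export
lostInterregionContacts <- function(m, firstRetained) {
  stopifnot(is(m, "ContactMap"))
  firstRetained <- as.integer(firstRetained)
  p <- m@pairs
  delI <- p$i < firstRetained
  delJ <- p$j < firstRetained
  list(lost = p[xor(delI, delJ), , drop = FALSE],
       removed = p[delI & delJ, , drop = FALSE],
       retained = p[!delI & !delJ, , drop = FALSE])
}

#' Count contacts between two residue ranges
#'
#' Number of contacts with one member in range \code{a} and the other in
#' range \code{b}. When the ranges coincide, pairs internal to the range are
#' counted once (the map stores unordered pairs). This is the numeric
#' reduction of region-pair "contact density": e.g. contacts between the
#' Delta133-deleted segment (94-132) and the C-terminal half of the DBD.
#'
#' @param m a \linkS4class{ContactMap}.
#' @param a,b inclusive residue ranges, each \code{c(first, last)} in author
#'   numbering.
#' @return integer contact count.
#' @examples
#' s <- genToyStructure(40, seed = 1)
#' m <- computeContactMap(s)
#' regionContactCount(m, c(1, 20), c(21, 40))
#' @export
regionContactCount <- function(m, a, b) {
  stopifnot(is(m, "ContactMap"))
  a <- .checkRange(a)
  b <- .checkRange(b)
  p <- m@pairs
  inA <- function(x) x >= a[1] & x <= a[2]
  inB <- function(x) x >= b[1] & x <= b[2]
  sum((inA(p$i) & inB(p$j)) | (inB(p$i) & inA(p$j)))
}

.checkRange <- function(r) {
  r <- as.integer(r)
  if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
    stop("a residue range must be c(first, last) with first <= last")
  r
}

#' Fraction of a domain deleted by a truncation
#'
#' Percentage of a domain's residues removed by an N-terminal truncation.
#' For the p53 DBD (94-292): truncation at 133 removes 39/199 = 19.6%
#' (about 20%), truncation at 160 removes 66/199 = 33.2% (about 33%).
#'
#' @param domain inclusive residue range \code{c(first, last)}.
#' @param firstRetained first residue number kept.
#' @return list with \code{percent} (exact) and \code{roundedPercent}
#'   (nearest integer).
#' @examples
#' domainLossFraction(c(94, 292), 133)  # 19.6% -> 20
#' domainLossFraction(c(94, 292), 160)  # 33.2% -> 33
#' @export
domainLossFraction <- function(domain, firstRetained) {
  domain <- .checkRange(domain)
  firstRetained <- as.integer(firstRetained)
  if (length(firstRetained) != 1L || is.na(firstRetained) ||
      firstRetained < 1L)
    stop("firstRetained must be a single integer >= 1")
  len <- domain[2] - domain[1] + 1L
  nLost <- max(0L, min(firstRetained - 1L, domain[2]) - domain[1] + 1L)
  pct <- 100 * nLost / len
  list(percent = pct, roundedPercent = as.integer(round(pct)))
}
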