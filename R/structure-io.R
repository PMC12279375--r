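#' Load a single protein chain from a PDB or mmCIF file
#'
#' Reads coordinates with bio3d, keeps standard polymer \code{ATOM} records
#' of one chain (hetero compounds and solvent are dropped), resolves
#' alternate locations to the highest-occupancy conformer, and preserves the
#' author residue numbering. Author numbering matters here: all p53 ranges
#' used downstream (DBD 94-292, aggregation region 251-257, truncation
#' starts 133/160) are author numbers.
#'
#' @param path PDB (\code{.pdb}, \code{.ent}) or mmCIF (\code{.cif},
#'   \code{.mmcif}) file.
#' @param chain chain identifier, default \code{"A"}.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' s <- genToyStructure(10, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePDB(s, f)
#' loadStructure(f, chain = "A")
#' @export
loadStructure <- function(path, chain = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
    else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse '", path,
                             "' as PDB/mmCIF: ", conditionMessage(e)))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  avail <- unique(atoms$chain)
  if (!chain %in% avail)
    stop("chain '", chain, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  # drop residues with insertion codes rather than invent numbering
  if ("insert" %in% names(atoms)) {
    ins <- !is.na(atoms$insert) & nzchar(atoms$insert)
    if (any(ins)) {
      warning(sum(ins), " atoms with insertion codes dropped")
      atoms <- atoms[!ins, , drop = FALSE]
    }
  }
  atoms$o[is.na(atoms$o)] <- 1
  # altloc resolution: within (resno, atom name) keep highest occupancy,
  # ties broken by altloc identifier order
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  key <- paste(atoms$resno, atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$resno, atoms$eleno), , drop = FALSE]

  element <- atoms$elesy
  bad <- is.na(element) | !nzchar(element)
  if (any(bad))  # fall back on the atom-name convention
    element[bad] <- substr(gsub("[^A-Za-z].*$", "", atoms$elety[bad]), 1, 1)
  out <- data.frame(resno = as.integer(atoms$resno), resid = atoms$resid,
                    elety = atoms$elety, element = toupper(element),
                    x = atoms$x, y = atoms$y, z = atoms$z, occ = atoms$o,
                    row.names = NULL)
  new("ProteinStructure", atoms = out, chain = chain, source = path)
}

#' Remove N-terminal residues to emulate an isoform truncation
#'
#' Returns the structure restricted to residues with author number greater
#' than or equal to \code{firstRetained}. \code{firstRetained = 133}
#' produces the Delta133p53 core-domain view of a full-length structure,
#' \code{160} the Delta160p53 view, and \code{1} is the identity.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param firstRetained first residue number kept (>= 1).
#' @return a new \linkS4class{ProteinStructure}; the input is unchanged.
#' @examples
#' s <- genToyStructure(30, seed = 1)
#' nResidues(applyTruncation(s, 11))  # 20
#' @export
applyTruncation <- function(s, firstRetained) {
  stopifnot(is(s, "ProteinStructure"))
  firstRetained <- as.integer(firstRetained)
  if (length(firstRetained) != 1L || is.na(firstRetained) ||
      firstRetained < 1L)
    stop("firstRetained must be a single integer >= 1")
  keep <- s@atoms$resno >= firstRetained
  if (!any(keep))
    stop("truncation at residue ", firstRetained,
         " removes every residue (structure ends at ",
         max(s@atoms$resno), ")")
  new("ProteinStructure", atoms = s@atoms[keep, , drop = FALSE],
      chain = s@chain, source = s@source)
}

#' Write a structure to a PDB file
#'
#' Thin wrapper over \code{bio3d::write.pdb} used mainly to materialize
#' generated toy structures for round-trip tests and external viewers.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(s, path) {
  stopifnot(is(s, "ProteinStructure"))
  a <- s@atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = rep(s@chain, nrow(a)), o = a$occ,
                   b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# C-alpha coordinate matrix (rows named by residue number); residues
# lacking a CA are reported via attribute "missing"
.caCoords <- function(s) {
  a <- s@atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  dup <- duplicated(ca$resno)
  if (any(dup)) ca <- ca[!dup, , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  attr(m, "missing") <- setdiff(unique(a$resno), ca$resno)
  m
}
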