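# Build a CA-only ProteinStructure from a coordinate matrix.
makeCaStructure <- function(xyz, resno = seq_len(nrow(xyz)),
                            resid = "ALA", element = "C",
                            elety = "CA") {
  atoms <- data.frame(resno = as.integer(resno),
                      resid = rep_len(resid, nrow(xyz)),
                      elety = rep_len(elety, nrow(xyz)),
                      element = rep_len(element, nrow(xyz)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, row.names = NULL)
  new("ProteinStructure", atoms = atoms, chain = "A", source = "test")
}

# Brute-force all-pairs contact oracle, independent of computeContactMap.
bruteContacts <- function(s, cutoff = 8, minSeparation = 2) {
  a <- s@atoms[s@atoms$elety == "CA", ]
  out <- data.frame(i = integer(), j = integer())
  for (p in seq_len(nrow(a))) {
    for (q in seq_len(nrow(a))) {
      if (q <= p) next
      d <- sqrt(sum((a[p, c("x", "y", "z")] - a[q, c("x", "y", "z")])^2))
      if (d <= cutoff && abs(a$resno[p] - a$resno[q]) >= minSeparation)
        out <- rbind(out, data.frame(i = min(a$resno[p], a$resno[q]),
                                     j = max(a$resno[p], a$resno[q])))
    }
  }
  out[order(out$i, out$j), , drop = FALSE]
}

# Monte-Carlo burial oracle for the SASA of one atom: random (not
# quasi-uniform) directions, so independent of the Fibonacci lattice.
mcAtomSasa <- function(xyz, radii, idx, probe = 1.4, nMC = 20000,
                      seed = 42) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * nMC), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rExp <- radii + probe
  pts <- sweep(dirs * rExp[idx], 2, xyz[idx, ], `+`)
  free <- rep(TRUE, nMC)
  for (j in seq_len(nrow(xyz))) {
    if (j == idx) next
    d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
    free <- free & d2 >= rExp[j]^2
  }
  mean(free) * 4 * pi * rExp[idx]^2
}

# Exhaustive ordered-4-tuple oracle for the tetramer composition: draw
# each of the 4 subunits independently (isoform with prob p) and tally
# isoform counts over all 2^4 ordered tuples.
enumerateComposition <- function(p) {
  counts <- numeric(5)
  for (t1 in 0:1) for (t2 in 0:1) for (t3 in 0:1) for (t4 in 0:1) {
    tup <- c(t1, t2, t3, t4)
    prob <- prod(ifelse(tup == 1, p, 1 - p))
    counts[sum(tup) + 1] <- counts[sum(tup) + 1] + prob
  }
  counts
}

# Activity oracle from the same enumeration.
enumerateActivity <- function(p, k, mode = "step") {
  pr <- enumerateComposition(p)
  i <- 0:4
  act <- if (mode == "step") as.numeric(i < k)
         else as.numeric(i < k) * (4 - i) / 4
  sum(pr * act)
}

# Write a minimal fixed-format PDB file from explicit fields.
writePdbFixture <- function(path, resno, x, y, z, resid = "ALA",
                            chain = "A", altloc = "", occ = 1,
                            name = "CA", element = "C") {
  n <- length(resno)
  resid <- rep_len(resid, n); altloc <- rep_len(altloc, n)
  occ <- rep_len(occ, n); name <- rep_len(name, n)
  element <- rep_len(element, n)
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name[i], altloc[i], resid[i], chain, resno[i],
            x[i], y[i], z[i], occ[i], 0, element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
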