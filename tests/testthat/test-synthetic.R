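test_that("every generator is byte-identical under a fixed seed", {
  s <- Scenario(seed = 42)
  expect_identical(genReporterDataset(s), genReporterDataset(s))
  expect_identical(genChipDataset(s), genChipDataset(s))
  expect_identical(genFractionationDataset(s), genFractionationDataset(s))
  expect_identical(genCaspaseDataset(s), genCaspaseDataset(s))
  expect_identical(genToyStructure(40, "compact_cluster", seed = 9),
                   genToyStructure(40, "compact_cluster", seed = 9))
  # different seeds do differ
  s2 <- Scenario(seed = 43)
  expect_false(identical(genReporterDataset(s), genReporterDataset(s2)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(genReporterDataset(Scenario())); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless reporter data reproduce the theoretical curve exactly", {
  s <- Scenario(cvReporter = 0)
  tab <- genReporterDataset(s)
  curve <- reporterInhibitionCurve(tab)
  theo <- theoreticalInhibitionCurve(3)
  expect_equal(curve@activity, theo@activity, tolerance = 1e-12)
  # control normalization equals baseline fold activation times activity
  norm <- normalizeReporter(tab)$summary
  expect_equal(norm$mean[!is.na(norm$ratio)],
               20 * attr(tab, "trueActivity"), ignore_attr = TRUE)
})

test_that("noiseless ChIP data recover the scenario enrichments exactly", {
  s <- Scenario(sdCt = 0)
  res <- estimateChipEnrichment(genChipDataset(s))
  truth <- attr(genChipDataset(s), "trueEnrichment")
  for (r in seq_len(nrow(res)))
    expect_equal(res$foldEnrichment[r],
                 truth[res$construct[r], res$promoter[r]],
                 tolerance = 1e-9)
})

test_that("noiseless fractionation and caspase data recover their factors", {
  s <- Scenario(cvFractionation = 0, cvCaspase = 0)
  cn <- estimateCnEnrichment(genFractionationDataset(s))
  expect_equal(unname(cn[c("D133p53", "D160p53")]), c(1.5, 1.5))
  expect_equal(unname(cn["FLp53"]), 1)
  expect_equal(estimateCaspaseFold(genCaspaseDataset(s)), 2.5)
  expect_equal(estimateCaspaseFold(genCaspaseDataset(s),
                                   construct = "FLp53+D133p53"), 1.3)
})

test_that("large-n noisy reporter means concentrate on the truth", {
  s <- Scenario(cvReporter = 0.1, nReplicates = 1000, seed = 8)
  tab <- genReporterDataset(s)
  curve <- reporterInhibitionCurve(tab)
  theo <- theoreticalInhibitionCurve(3)
  expect_equal(curve@activity, theo@activity, tolerance = 0.02)
})

test_that("ideal helix geometry has the alpha-helical contact pattern", {
  s <- genToyStructure(20, "ideal_helix")
  ca <- s@atoms
  d <- function(i, j) sqrt(sum((ca[i, c("x", "y", "z")] -
                                  ca[j, c("x", "y", "z")])^2))
  expect_lt(d(1, 4), 8)    # i, i+3
  expect_lt(d(1, 5), 8)    # i, i+4
  expect_gt(d(1, 11), 8)   # i, i+10 is far along the axis
  expect_equal(d(1, 3), 5.43, tolerance = 0.01)  # i, i+2 geometry
  m <- computeContactMap(s)
  p <- contacts(m)
  expect_true(all(p$j - p$i <= 5))   # helix contacts are local
  expect_true(any(p$j - p$i == 2))   # (i, i+2) within 8 A at min sep 2
})

test_that("compact clusters respect the minimum inter-residue distance", {
  s <- genToyStructure(60, "compact_cluster", seed = 5)
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")])
  dmin <- min(dist(xyz))
  expect_gte(dmin, 3.8 - 1e-9)
  expect_error(genToyStructure(2), ">= 3")
})

test_that("the default scenario pipeline recovers the generating threshold", {
  # reporter table -> control normalization -> inhibition curve ->
  # ExpDec1 fit (smoothness check) -> minimal-threshold inference
  kHat <- integer(100)
  for (i in 1:100) {
    s <- Scenario(cvReporter = 0.05, seed = 1000L + i)
    curve <- reporterInhibitionCurve(genReporterDataset(s))
    kHat[i] <- inferMinimalThreshold(curve)$kMin
  }
  modal <- as.integer(names(which.max(table(kHat))))
  expect_identical(modal, 3L)
  # the experimental curve is well described by a one-phase decay
  s <- Scenario(cvReporter = 0.05, seed = 77)
  curve <- reporterInhibitionCurve(genReporterDataset(s))
  fit <- fitExpDec1(curve@ratio, curve@activity)
  expect_true(fit@converged)
  expect_lt(fit@rss, 0.05)
})

test_that("generated PDB fixtures re-parse losslessly", {
  s <- genToyStructure(25, "compact_cluster", seed = 13)
  f <- tempfile(fileext = ".pdb")
  writeStructurePDB(s, f)
  s2 <- loadStructure(f)
  expect_identical(residues(s2), residues(s))
  m1 <- contacts(computeContactMap(s))[, c("i", "j")]
  m2 <- contacts(computeContactMap(s2))[, c("i", "j")]
  expect_equal(m1, m2)
})
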