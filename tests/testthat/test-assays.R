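makeReporterTab <- function(conds, lums) {
  data.frame(condition = rep(conds, each = 3), replicate = rep(1:3,
             length(conds)), luminescence = lums)
}

test_that("reporter normalization divides by the control mean", {
  tab <- makeReporterTab(c("pcDNA3.1", "FLp53"),
                         c(100, 100, 100, 250, 250, 250))
  res <- normalizeReporter(tab)
  expect_equal(res$summary$mean[res$summary$condition == "FLp53"], 2.5)
  expect_equal(res$summary$sd[res$summary$condition == "FLp53"], 0)
  expect_equal(res$summary$mean[res$summary$condition == "pcDNA3.1"], 1)
  expect_equal(res$summary$n, c(3L, 3L))
})

test_that("reporter normalization matches hand computation and is scale-invariant", {
  set.seed(12)
  lums <- c(runif(3, 80, 120), runif(3, 200, 400), runif(3, 30, 70))
  tab <- makeReporterTab(c("pcDNA3.1", "A", "B"), lums)
  res <- normalizeReporter(tab)
  cm <- mean(lums[1:3])
  expect_equal(res$summary$mean[res$summary$condition == "A"],
               mean(lums[4:6] / cm))
  expect_equal(res$summary$sd[res$summary$condition == "B"],
               sd(lums[7:9] / cm))
  tab2 <- tab; tab2$luminescence <- tab$luminescence * 37.5
  expect_equal(normalizeReporter(tab2)$summary$mean, res$summary$mean)
  expect_error(normalizeReporter(makeReporterTab("A", rep(1, 3)),
                                 control = "missing"), "not present")
  zero <- makeReporterTab("pcDNA3.1", rep(0, 3))
  expect_error(normalizeReporter(zero), "positive")
})

test_that("percent input follows the base-2 dilution arithmetic", {
  # independent algebraic oracle: PI = inputFraction * 100 * 2^(ctInput-ctIp)
  oracle <- function(ip, inp, f) f * 100 * 2^(inp - ip)
  expect_equal(chipPercentInput(25, 20, 0.05), oracle(25, 20, 0.05))
  expect_equal(chipPercentInput(25, 20, 0.05), 100 * 2^(15.678 - 25),
               tolerance = 1e-4)
  set.seed(3)
  ip <- runif(20, 18, 30); inp <- runif(20, 15, 22)
  expect_equal(chipPercentInput(ip, inp, 0.01), oracle(ip, inp, 0.01))
  expect_error(chipPercentInput(25, 20, 0), "inputFraction")
  expect_error(chipPercentInput(NA, 20, 0.05), "finite")
})

test_that("fold enrichment is 1 for sample == control and doubles per cycle", {
  pinCtrl <- chipPercentInput(25, 20, 0.05)
  expect_equal(chipRelativeEnrichment(25, 20, 0.05, pinCtrl), 1)
  f1 <- chipRelativeEnrichment(24, 20, 0.05, pinCtrl)
  f2 <- chipRelativeEnrichment(23, 20, 0.05, pinCtrl)
  expect_equal(f2 / f1, 2)
  # invariance to a shared input fraction
  a <- chipRelativeEnrichment(23, 20, 0.05,
                              chipPercentInput(25, 20, 0.05))
  b <- chipRelativeEnrichment(23, 20, 0.20,
                              chipPercentInput(25, 20, 0.20))
  expect_equal(a, b)
  expect_error(chipRelativeEnrichment(23, 20, 0.05, 0), "positive")
})

test_that("table-level ChIP enrichment normalizes per promoter", {
  tab <- data.frame(promoter = rep(c("p21", "BAX"), each = 4),
                    construct = rep(c("pcDNA3.1", "FLp53"), 4),
                    replicate = 1,
                    ct_ip = c(26, 23, 26, 23, 28, 27, 28, 27),
                    ct_input = 20, input_fraction = 0.05)
  res <- estimateChipEnrichment(tab)
  expect_equal(res$foldEnrichment[res$promoter == "p21" &
                                  res$construct == "FLp53"], 8)
  expect_equal(res$foldEnrichment[res$promoter == "BAX" &
                                  res$construct == "FLp53"], 2)
  expect_error(estimateChipEnrichment(tab, control = "missing"),
               "not present")
})

test_that("response-element annotation follows the RRRCWWGYYY consensus", {
  perfect <- annotateResponseElement("GAACATGTCC")
  expect_equal(perfect$mismatchCount, 0L)
  expect_identical(perfect$display, "GAACATGTCC")
  one <- annotateResponseElement("GAACATGTCA")
  expect_equal(one$mismatchCount, 1L)
  expect_false(one$match[10])
  expect_identical(one$display, "GAACATGTCa")
  expect_error(annotateResponseElement("GAACATGTCN"), "non-ACGT")
  expect_error(annotateResponseElement("GAACATG"), "remainder 7")
})

test_that("annotation mask equals the per-position IUPAC membership oracle", {
  allowed <- list(R = c("A", "G"), W = c("A", "T"), Y = c("C", "T"),
                  C = "C", G = "G")
  pat <- strsplit("RRRCWWGYYY", "")[[1]]
  set.seed(21)
  for (rep in 1:5) {
    seqv <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    res <- annotateResponseElement(paste(seqv, collapse = ""))
    oracle <- vapply(seq_along(seqv), function(i)
      seqv[i] %in% allowed[[pat[(i - 1) %% 10 + 1]]], logical(1))
    expect_identical(res$match, oracle)
    expect_equal(res$mismatchCount, sum(!oracle))
  }
})

test_that("C/N ratios are marker-normalized and reference-scaled", {
  fl <- fractionationCNRatio(1.0, 1.0, 2.0, 1.0)
  expect_equal(fl, 0.5)
  iso <- fractionationCNRatio(1.5, 1.0, 2.0, 1.0, referenceRatio = fl)
  expect_equal(iso, 1.5)
  expect_equal(fractionationCNRatio(3, 3, 3, 3), 1)
  # rescaling both markers by any constant cancels
  expect_equal(fractionationCNRatio(1.5, 2.7, 2.0, 2.7,
                                    referenceRatio = fl),
               fractionationCNRatio(1.5, 1.0, 2.0, 1.0,
                                    referenceRatio = fl))
  expect_error(fractionationCNRatio(0, 1, 1, 1), "positive")
})

test_that("caspase fold subtracts blank and normalizes to control", {
  expect_equal(caspaseFold(3500, 500, 1700), 2.5)
  expect_equal(caspaseFold(1700, 500, 1700), 1)
  # triplicate means match the elementwise oracle
  s <- c(3300, 3500, 3700); bl <- c(480, 500, 520)
  ct <- c(1600, 1700, 1800)
  expect_equal(caspaseFold(s, bl, ct),
               (mean(s) - mean(bl)) / (mean(ct) - mean(bl)))
  expect_error(caspaseFold(3500, 1700, 1700), "positive")
})

test_that("Student's t-test matches the pooled-variance closed form", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- twoSampleTTest(a, b)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  tOracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$statistic, tOracle)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 2 * pt(tOracle, 4))
  expect_equal(res$p.value, 0.0214, tolerance = 1e-2)
})

test_that("t-test degenerate and variant behaviour", {
  idA <- c(1, 2, 3)
  same <- twoSampleTTest(idA, idA)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  degEq <- twoSampleTTest(c(2, 2, 2), c(2, 2, 2))
  expect_true(degEq$degenerate)
  expect_equal(degEq$p.value, 1)
  degNe <- twoSampleTTest(c(2, 2, 2), c(3, 3, 3))
  expect_true(is.infinite(degNe$statistic))
  expect_equal(degNe$p.value, 0)
  # Welch equals Student at equal variance and n
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  st <- twoSampleTTest(a, b, "student")
  we <- twoSampleTTest(a, b, "welch")
  expect_equal(we$statistic, st$statistic)
  expect_equal(we$df, st$df)
  expect_error(twoSampleTTest(1, c(1, 2)), "at least 2")
})
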