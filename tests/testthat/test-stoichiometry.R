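test_that("expression ratios convert to monomer fractions", {
  expect_equal(isoformFraction(0), 0)
  expect_equal(isoformFraction(1), 0.5)
  expect_equal(isoformFraction(10), 10 / 11)
  expect_error(isoformFraction(-1), "non-negative")
})

test_that("tetramer composition matches the ordered-4-tuple enumeration", {
  expect_equal(unname(compositionDistribution(0)), c(1, 0, 0, 0, 0))
  expect_equal(unname(compositionDistribution(0.5)),
               c(1, 4, 6, 4, 1) / 16)
  for (p in c(seq(0.1, 0.9, by = 0.1), 5 / 6)) {
    d <- compositionDistribution(p)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(unname(d), enumerateComposition(p), tolerance = 1e-12,
                 label = paste("p =", p))
  }
  expect_error(compositionDistribution(1.2), "\\[0, 1\\]")
})

test_that("pool activity matches the enumeration oracle", {
  expect_equal(tetramerActivity(0.5, k = 3), 11 / 16)
  expect_equal(tetramerActivity(5 / 6, k = 2), 21 / 1296)
  expect_equal(tetramerActivity(0, k = 5), 1)     # sentinel: never inactive
  expect_equal(tetramerActivity(0.7, k = 5), 1)
  for (p in c(0.2, 0.5, 5 / 6)) for (k in 1:4)
    for (mode in c("step", "proportional"))
      expect_equal(tetramerActivity(p, k, mode),
                   enumerateActivity(p, k, mode),
                   label = paste(p, k, mode))
})

test_that("activity is monotone: decreasing in p, increasing in k, 1 at p = 0", {
  ps <- seq(0, 0.95, by = 0.05)
  for (k in 1:4) {
    act <- vapply(ps, tetramerActivity, numeric(1), k = k)
    expect_true(all(diff(act) <= 1e-12), label = paste("k =", k))
    expect_equal(act[1], 1)
  }
  for (p in c(0.3, 0.6, 0.9)) {
    byK <- vapply(1:4, function(k) tetramerActivity(p, k), numeric(1))
    expect_true(all(diff(byK) > 0), label = paste("p =", p))
  }
})

test_that("theoretical inhibition curves match closed-form binomial sums", {
  c3 <- theoreticalInhibitionCurve(3)
  expect_equal(curvePoints(c3)$activity,
               c(1, 11 / 16,
                 sum(dbinom(0:2, 4, 5 / 6)),
                 sum(dbinom(0:2, 4, 10 / 11))),
               tolerance = 1e-12)
  c1 <- theoreticalInhibitionCurve(1, ratios = c(0, 1))
  expect_equal(curvePoints(c1)$activity[2], 0.5^4)
  expect_error(theoreticalInhibitionCurve(3, ratios = c(1, 0, 5)),
               "start at 0|increasing")
  expect_error(theoreticalInhibitionCurve(3, ratios = c(0, 5, 1)),
               "increasing")
})

test_that("curves are strictly ordered by threshold at every nonzero ratio", {
  for (r in c(0.5, 1, 5, 10)) {
    act <- vapply(1:4, function(k) {
      curvePoints(theoreticalInhibitionCurve(k, ratios = c(0, r)))$activity[2]
    }, numeric(1))
    expect_true(all(diff(act) > 0), label = paste("ratio", r))
  }
})

test_that("compartment-adjusted pools dilute the isoform fraction", {
  mix <- subunitMix(1, 5, phiFL = 0.5, phiIso = 0.25)
  expect_equal(nuclearAdjustedFraction(mix), 1.25 / 1.75)
  # equal partitioning reduces to the naive expression fraction
  mix2 <- subunitMix(2, 6, phiFL = 0.4, phiIso = 0.4)
  expect_equal(nuclearAdjustedFraction(mix2), isoformFraction(3))
  # complete isoform sequestration empties the nuclear isoform pool
  expect_equal(nuclearAdjustedFraction(subunitMix(1, 5, seqIso = 1)), 0)
  expect_error(nuclearAdjustedFraction(subunitMix(1, 1, phiFL = 0,
                                                  phiIso = 0)),
               "zero")
})

test_that("adjusted fraction never exceeds naive when isoforms are retained less", {
  set.seed(99)
  for (i in 1:50) {
    eFL <- runif(1, 0.1, 5); eIso <- runif(1, 0.1, 5)
    phiFL <- runif(1); phiIso <- runif(1, 0, phiFL)
    seqFL <- runif(1, 0, 0.5); seqIso <- runif(1, seqFL, 1)
    mix <- subunitMix(eFL, eIso, phiFL, phiIso, seqFL, seqIso)
    naive <- isoformFraction(eIso / eFL)
    if (phiIso == 0 && seqIso == 1) next
    expect_lte(nuclearAdjustedFraction(mix), naive + 1e-12)
  }
})

test_that("threshold inference recovers the generating k on noiseless curves", {
  for (k in 1:4) {
    theo <- theoreticalInhibitionCurve(k)
    exp <- new("InhibitionCurve", ratio = theo@ratio,
               activity = theo@activity, kind = "experimental")
    res <- inferMinimalThreshold(exp)
    expect_identical(res$kMin, k, label = paste("k =", k))
    if (k > 1) expect_true(all(res$rejected[seq_len(k - 1)]))
  }
  # the k = 3 self-curve rejects the two-subunit hypothesis
  theo3 <- theoreticalInhibitionCurve(3)
  exp3 <- new("InhibitionCurve", ratio = theo3@ratio,
              activity = theo3@activity, kind = "experimental")
  expect_true(inferMinimalThreshold(exp3)$rejected[["k2"]])
})

test_that("a flat no-inhibition curve rejects every threshold (sentinel 5)", {
  exp <- new("InhibitionCurve", ratio = c(0, 1, 5, 10),
             activity = c(1, 1, 1, 1), kind = "experimental")
  res <- inferMinimalThreshold(exp)
  expect_identical(res$kMin, 5L)
  expect_true(all(res$rejected))
})

test_that("inference demands a normalized curve and enough ratios", {
  expect_error(inferMinimalThreshold(
    new("InhibitionCurve", ratio = c(0, 1), activity = c(1, 0.7),
        kind = "experimental")), "two nonzero")
  expect_error(inferMinimalThreshold(
    new("InhibitionCurve", ratio = c(0, 1, 5), activity = c(2, 1, 0.5),
        kind = "experimental")), "not normalized")
  expect_error(inferMinimalThreshold(
    new("InhibitionCurve", ratio = c(1, 5, 10),
        activity = c(0.7, 0.2, 0.1), kind = "experimental")),
    "ratio-0")
})
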