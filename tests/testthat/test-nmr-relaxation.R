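# Exponential fitting, NOE, the R1R2 product, chemical shift perturbations,
# and trimmed-mean outlier calling.

test_that("noiseless decays are fitted exactly", {
  s <- simulateDecayCurves(2.0, nResidues = 1, noiseSd = 0, seed = 1)
  r <- s@records
  fit <- fitExponentialDecay(r$delay_s, r$intensity)
  expect_equal(fit$rate, 2.0, tolerance = 1e-6)
  expect_equal(fit$I0, 100, tolerance = 1e-6)
  expect_false(fit$negative)
})

test_that("constant intensities fit to rate 0; degenerate inputs error", {
  fit <- fitExponentialDecay(c(0, 0.1, 0.5, 1), rep(80, 4))
  expect_equal(fit$rate, 0, tolerance = 1e-8)
  expect_error(fitExponentialDecay(c(0, 0, 0.1), c(1, 1, 0.5)),
               "distinct delays")
  expect_error(fitExponentialDecay(c(0, 0.1, 0.2), c(0, 0, 0)),
               "all zero")
})

test_that("growing intensities are flagged negative, not clamped", {
  t <- c(0, 0.2, 0.4, 0.8)
  fit <- fitExponentialDecay(t, 50 * exp(0.9 * t))
  expect_true(fit$negative)
  expect_equal(fit$rate, -0.9, tolerance = 1e-6)
})

test_that("replicate noise estimate recovers the planted noise level", {
  s <- simulateDecayCurves(rep(1.5, 400), noiseSd = 0.02, I0 = 100,
                           seed = 12)
  est <- replicateNoiseSd(s)
  expect_lt(abs(est - 2) / 2, 0.15)
  s0 <- simulateDecayCurves(1.5, replicateDelays = numeric(0), seed = 1)
  expect_true(is.na(replicateNoiseSd(s0)))
})

test_that("per-residue fits with replicate weighting are calibrated", {
  s <- simulateDecayCurves(rep(2.0, 60), noiseSd = 0.02, seed = 77)
  rates <- fitRelaxationRates(s)
  expect_equal(nrow(rates), 60)
  err <- rates$rate - 2.0
  expect_lt(abs(mean(err)) / 2.0, 0.01)        # unbiased within 1%
  covered <- abs(err) < 3 * rates$rateSd
  expect_gte(mean(covered), 0.95)
})

test_that("NOE ratios preserve sign and reject zero references", {
  expect_equal(computeNOE(0.8, 1.0)$noe, 0.8)
  expect_equal(computeNOE(1.0, 1.0)$noe, 1.0)
  expect_equal(computeNOE(-0.2, 1.0)$noe, -0.2)
  expect_error(computeNOE(1, 0), "zero reference")
  withSd <- computeNOE(0.8, 1.0, saturatedSd = 0.02, referenceSd = 0.02)
  expect_equal(withSd$noeSd, 0.8 * sqrt((0.02 / 0.8)^2 + 0.02^2),
               tolerance = 1e-12)
})

test_that("R1R2 product and its first-order uncertainty are exact", {
  r1 <- data.frame(residue = c(1, 2, 3), rate = c(1.2, 0, 1.0),
                   rateSd = c(0.05, 0.01, 0.1))
  r2 <- data.frame(residue = c(1, 2, 3), rate = c(10, 10, 10),
                   rateSd = c(0.5, 0.5, 1))
  rr <- r1r2Product(r1, r2)
  expect_equal(rr$r1r2, c(12, 0, 10))
  expect_equal(rr$r1r2Sd[3], sqrt((0.1 * 10)^2 + (1.0 * 1)^2),
               tolerance = 1e-12)
  # missing rate: residue skipped and reported
  r1$rate[2] <- NA
  rr2 <- r1r2Product(r1, r2)
  expect_equal(nrow(rr2), 2)
  expect_equal(attr(rr2, "skipped"), 2)
})

test_that("combined CSP closed form and linear nitrogen scaling", {
  expect_equal(combinedCSP(0, 0), 0)
  expect_equal(combinedCSP(0.05, 0.5), 0.08602325, tolerance = 1e-7)
  # nitrogen-only perturbation scales linearly with the weight
  expect_equal(combinedCSP(0, 0.5, w = 0.28),
               2 * combinedCSP(0, 0.5, w = 0.14), tolerance = 1e-12)
})

test_that("shift perturbations flag vanished peaks as broadened", {
  ref <- data.frame(residue = 1:4, dH = c(8.1, 8.2, 8.3, 8.4),
                    dN = c(120, 121, 122, 123))
  var <- data.frame(residue = c(1, 2, 4), dH = c(8.1, 8.25, 8.4),
                    dN = c(120, 121, 123.5))
  sp <- shiftPerturbations(ref, var)
  expect_true(sp$broadened[sp$residue == 3])
  expect_equal(sp$csp[sp$residue == 2], combinedCSP(0.05, 0))
  expect_equal(sp$csp[sp$residue == 1], 0)
})

test_that("threshold profile isolates a single spike and ignores offsets", {
  v <- c(rep(0, 9), 10)
  names(v) <- paste0("r", 1:10)
  th <- thresholdProfile(v)
  expect_equal(th$significant, "r10")
  expect_equal(thresholdProfile(rep(1, 12))$significant, integer(0))
  # adding a constant shifts the mean, not the significant set
  th2 <- thresholdProfile(v + 100)
  expect_equal(th2$significant, "r10")
  expect_error(thresholdProfile(1:5), "at least 10")
})

test_that("trimmed-mean statistics match the brute-force oracle", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    v <- rnorm(n, sd = runif(1, 0.5, 3)) + rexp(n) * sample(0:1, 1)
    names(v) <- paste0("r", seq_len(n))
    oracle <- bruteTrimFlags(v)
    ref <- setNames(rnorm(n), names(v))
    rep <- correlationOutliers(ref, ref + v)   # deviations equal v
    expect_equal(rep@trimmedMean, oracle$trimmedMean, tolerance = 1e-12)
    expect_equal(rep@sigma, oracle$sigma, tolerance = 1e-12)
    expect_identical(rep@flagged, unname(oracle$flags))
  }
})

test_that("correlation outliers: identity, planted spike, rank invariance", {
  ref <- setNames(seq(1, 5, length.out = 30), paste0("r", 1:30))
  same <- correlationOutliers(ref, ref)
  expect_equal(sum(same@flagged), 0)
  expect_equal(same@rho, 1.0)

  spiked <- ref
  spiked["r7"] <- spiked["r7"] + 50
  rep <- correlationOutliers(ref, spiked)
  expect_equal(flaggedResidues(rep), "r7")

  # monotone transform: rho stays 1 despite nonzero deviations
  mono <- correlationOutliers(ref, ref^3)
  expect_equal(mono@rho, 1.0)
  expect_gt(max(abs(mono@deviation)), 0)

  expect_error(correlationOutliers(ref[1:5], ref[1:5]),
               "insufficient overlap")
  # flags invariant under residue reordering
  perm <- sample(names(ref))
  rep2 <- correlationOutliers(ref[perm], spiked[perm])
  expect_setequal(flaggedResidues(rep2), flaggedResidues(rep))
  # perpendicular mode only rescales deviations by sqrt(2)
  repP <- correlationOutliers(ref, spiked, perpendicular = TRUE)
  expect_equal(repP@deviation * sqrt(2), rep@deviation, tolerance = 1e-12)
  expect_identical(repP@flagged, rep@flagged)
})

test_that("relaxation tables and Sparky peak lists round-trip from disk", {
  s <- simulateDecayCurves(c(1.1, 2.2), noiseSd = 0.01, seed = 6)
  p <- tempfile(fileext = ".csv")
  writeRelaxationCSV(s, p)
  back <- readRelaxationCSV(p, "T1")
  expect_equal(back@records$intensity, s@records$intensity,
               tolerance = 1e-12)

  pk <- tempfile(fileext = ".list")
  writeLines(c(" Assignment  w1      w2     Height",
               " S62N-H     121.3    8.21   15000",
               " F100N-H    118.9    7.95   12000"), pk)
  peaks <- readSparkyPeaks(pk)
  expect_equal(peaks$residue, c(62L, 100L))
  expect_equal(peaks$dN, c(121.3, 118.9))
  expect_equal(peaks$dH, c(8.21, 7.95))
})
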