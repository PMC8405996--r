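# Displacement extraction, the KSG mutual-information estimator against the
# Gaussian closed form, and the generalized correlation map.

test_that("static and rigidly rotating trajectories give zero displacement", {
  top <- makeSyntheticTrimer(nRes = 6)
  xyz <- as.matrix(atoms(top)[, c("x", "y", "z")])
  nf <- 10
  static <- array(rep(t(xyz), nf), dim = c(3, nrow(xyz), nf))
  static <- aperm(static, c(3, 2, 1))
  traj <- new("Trajectory", coords = static, topology = top)
  d <- extractDisplacements(traj)
  expect_lt(max(abs(d@samples)), 1e-10)

  rot <- traj
  for (f in seq_len(nf)) {
    R <- testRotation(angle = 0.1 * f)
    rot@coords[f, , ] <- xyz %*% t(R)
  }
  d2 <- extractDisplacements(rot)
  expect_lt(max(abs(d2@samples)), 1e-6)
})

test_that("a planted single-residue wobble is recovered to within 2%", {
  top <- makeSyntheticTrimer(nRes = 50)
  a <- atoms(top)
  ca <- which(a$elety == "CA")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nf <- 4000
  co <- array(rep(t(xyz), nf), dim = c(3, nrow(xyz), nf))
  co <- aperm(co, c(3, 2, 1))
  sdPlanted <- 1.0
  wob <- withr::with_seed(5, rnorm(nf, 0, sdPlanted))
  co[, ca[10], 1] <- co[, ca[10], 1] + wob
  traj <- new("Trajectory", coords = co, topology = top)
  d <- extractDisplacements(traj)
  got <- sd(d@samples[, 10, 1])
  expect_lt(abs(got - sdPlanted) / sdPlanted, 0.02)
})

test_that("estimator errors: empty selection, length mismatch, undersampling", {
  top <- makeSyntheticTrimer(nRes = 4)
  xyz <- as.matrix(atoms(top)[, c("x", "y", "z")])
  co <- aperm(array(rep(t(xyz), 3), dim = c(3, nrow(xyz), 3)), c(3, 2, 1))
  traj <- new("Trajectory", coords = co, topology = top)
  expect_error(extractDisplacements(traj, selection = "calpha",
                                    window = 1), "at least 2 frames")
  x <- matrix(rnorm(300), 100); y <- matrix(rnorm(303), 101)
  expect_error(mutualInformation(x, y, minSamples = 10), "equal sample")
  expect_error(mutualInformation(x, x[, , drop = FALSE]), "undersampled")
})

test_that("independent 3-vectors give near-zero mutual information", {
  s <- simulateCorrelatedTrajectory(1e4, 2, seed = 21)
  mi <- mutualInformation(s@samples[, 1, ], s@samples[, 2, ])
  expect_lt(as.numeric(mi), 0.05)
  expect_false(attr(mi, "degenerate"))
})

test_that("KSG recovers the Gaussian closed form at rho = 0.6", {
  C <- matrix(c(1, 0.6, 0.6, 1), 2)
  s <- simulateCorrelatedTrajectory(1e5, 2, C, seed = 31)
  mi <- as.numeric(mutualInformation(s@samples[, 1, ], s@samples[, 2, ]))
  expect_lt(abs(mi - gaussianMutualInformation(0.6)), 0.1)
})

test_that("histogram cross-check agrees with the closed form loosely", {
  C <- matrix(c(1, 0.6, 0.6, 1), 2)
  s <- simulateCorrelatedTrajectory(2e4, 2, C, seed = 32)
  mi <- as.numeric(mutualInformation(s@samples[, 1, ], s@samples[, 2, ],
                                     method = "histogram", bins = 6,
                                     maxSamples = 2e4))
  expect_lt(abs(mi - gaussianMutualInformation(0.6)), 0.25)
  # and it clearly separates a correlated from an independent pair
  s0 <- simulateCorrelatedTrajectory(2e4, 2, seed = 33)
  mi0 <- as.numeric(mutualInformation(s0@samples[, 1, ], s0@samples[, 2, ],
                                      method = "histogram", bins = 6,
                                      maxSamples = 2e4))
  expect_lt(mi0, mi / 2)
})

test_that("identical series are capped at iMax and flagged degenerate", {
  s <- simulateCorrelatedTrajectory(2000, 1, matrix(1), seed = 2)
  x <- s@samples[, 1, ]
  mi <- mutualInformation(x, x)
  expect_equal(as.numeric(mi), 20)
  expect_true(attr(mi, "degenerate"))
})

test_that("mutual information is symmetric and respects added noise", {
  C <- matrix(c(1, 0.7, 0.7, 1), 2)
  s <- simulateCorrelatedTrajectory(4000, 2, C, seed = 13)
  x <- s@samples[, 1, ]; y <- s@samples[, 2, ]
  expect_identical(as.numeric(mutualInformation(x, y)),
                   as.numeric(mutualInformation(y, x)))
  # data-processing sanity: independent noise on y cannot increase MI
  noisy <- y + withr::with_seed(3, matrix(rnorm(length(y), 0, 1), nrow(y)))
  mi0 <- as.numeric(mutualInformation(x, y))
  mi1 <- as.numeric(mutualInformation(x, noisy))
  expect_lt(mi1, mi0 + 0.05)
})

test_that("generalized correlation closed-form values and monotonicity", {
  expect_equal(generalizedCorrelation(0), 0)
  expect_equal(generalizedCorrelation(1.5326), 0.800, tolerance = 1e-4)
  expect_equal(generalizedCorrelation(10), 0.99936, tolerance = 1e-5)
  mi <- seq(0, 12, by = 0.25)
  g <- generalizedCorrelation(mi)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < 1))
  expect_error(generalizedCorrelation(-0.1), ">= 0")
})

test_that("correlation matrix finds a planted pair and stays symmetric", {
  C <- diag(5)
  C[1, 5] <- C[5, 1] <- 0.9
  s <- simulateCorrelatedTrajectory(1e4, 5, C, seed = 17)
  res <- correlationMatrix(s)
  g <- generalizedCorrelationMatrix(res)
  expect_equal(g, t(g))
  expect_equal(unname(diag(g)), rep(1, 5))
  off <- g; diag(off) <- 0
  top <- which(off == max(off), arr.ind = TRUE)[1, ]
  expect_setequal(unname(top), c(1, 5))
  expect_lt(abs(g[1, 5] - 0.9), 0.05)
  # all truly independent pairs stay low
  indep <- off[cbind(c(1, 2, 2, 3), c(2, 3, 4, 4))]
  expect_true(all(indep < 0.1))
})

test_that("residue relabeling permutes the matrix consistently", {
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.8
  s <- simulateCorrelatedTrajectory(3000, 3, C, seed = 23)
  res <- correlationMatrix(s, maxSamples = 3000, minSamples = 100)
  perm <- c(3, 1, 2)
  sPerm <- new("DisplacementSeries", samples = s@samples[, perm, ],
               labels = s@labels[perm])
  resPerm <- correlationMatrix(sPerm, maxSamples = 3000, minSamples = 100)
  expect_equal(resPerm@gcorr, res@gcorr[perm, perm], tolerance = 1e-12)
})

test_that("monomer blocks carve out chain submatrices", {
  s <- simulateCorrelatedTrajectory(1200, 4, seed = 3)
  s@labels <- c("A:1", "A:2", "B:1", "B:2")
  res <- correlationMatrix(s, maxSamples = 1200)
  expect_equal(dim(monomerBlock(res, "A")), c(2, 2))
  expect_equal(dim(monomerBlock(res, "A", "B")), c(2, 2))
  expect_equal(monomerBlock(res, "A", "B")["A:1", "B:2"],
               res@gcorr["A:1", "B:2"])
})

test_that("multi-model PDB trajectories round-trip through disk", {
  fix <- simulateChannelFrame(eqTriangle(8, 10), eqTriangle(8, 0),
                              nInside = 2, nOutside = 1, nFrames = 3,
                              seed = 4)
  path <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(fix$trajectory, path)
  back <- readTrajectoryPDB(path)
  expect_equal(nFrames(back), 3)
  expect_equal(back@coords, fix$trajectory@coords, tolerance = 1e-3)
  expect_equal(atoms(back)$resid, atoms(fix$trajectory)$resid)
})
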