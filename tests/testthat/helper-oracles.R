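# Independent oracles and small fixture builders used across the suite.

# Horn's quaternion-based optimal superposition: an implementation of rigid
# least-squares alignment independent of the package's SVD-based Kabsch.
quaternionSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  S <- crossprod(A, B)  # S[i,j] = sum_k A[k,i] B[k,j]
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  moved <- A %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((moved - B)^2))))
}

# brute-force sort-trim-flag oracle for the trimmed-mean outlier rule:
# drop floor(0.05 n) values from each end of the sorted vector, take the
# mean, flag |v - tm| > nSigma * sd(all v)
bruteTrimFlags <- function(v, nSigma = 1.5) {
  n <- length(v)
  srt <- sort(v)
  k <- floor(0.05 * n)
  tm <- mean(srt[(k + 1):(n - k)])
  s <- sd(v)
  list(trimmedMean = tm, sigma = s, flags = abs(v - tm) > nSigma * s)
}

# equilateral gate triangle of given side length centred on the z axis
eqTriangle <- function(side, z) {
  r <- side / sqrt(3)
  th <- c(90, 210, 330) * pi / 180
  cbind(r * cos(th), r * sin(th), z)
}

# gates-only trajectory (chains A/B/C, upper resno 100, lower resno 42)
gateTrajectory <- function(upperSide, lowerSide = upperSide, height = 10,
                           nFramesOut = 2) {
  fix <- simulateChannelFrame(eqTriangle(upperSide, height),
                              eqTriangle(lowerSide, 0),
                              nInside = 0, nOutside = 0,
                              nFrames = nFramesOut, seed = 1)
  fix$trajectory
}

# a rigidly moved copy of a trajectory (same motion applied to every frame)
rigidlyMove <- function(traj, rotation, translation) {
  co <- traj@coords
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- sweep(co[f, , ] %*% t(rotation), 2, translation, `+`)
  methods::new("Trajectory", coords = co, topology = traj@topology)
}

# fixed proper rotation used in several invariance tests
testRotation <- function(angle = 0.7, axis = c(1, 2, 3)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# hand-written 3-atom PDB fixture
writeToyPDB <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       3.200   3.400   3.000  1.00 10.00           C",
    "END"), path)
  path
}

# single-donor/single-acceptor trajectory: serine OG-HG donor on residue 1,
# backbone O acceptor on residue 2; bond geometry holds in `hit` of the
# frames (acceptor at 2.8 A collinear) and fails in the rest (3.5 A)
hbondFixture <- function(nFrame = 100, hit = 83) {
  top <- data.frame(
    chain = "A", resno = c(1L, 1L, 2L), resid = c("SER", "SER", "GLY"),
    elety = c("OG", "HG", "O"), element = c("O", "H", "O"), occ = 1,
    x = 0, y = 0, z = 0)
  model <- methods::new("StructureModel", atoms = top, source = "synthetic")
  coords <- array(0, dim = c(nFrame, 3, 3))
  for (f in seq_len(nFrame)) {
    coords[f, 1, ] <- c(0, 0, 0)         # OG
    coords[f, 2, ] <- c(0.97, 0, 0)      # HG
    coords[f, 3, ] <- if (f <= hit) c(2.8, 0, 0) else c(3.5, 0, 0)
  }
  methods::new("Trajectory", coords = coords, topology = model)
}

# coordinate matrix of all atoms with a given atom name
selectAtomsForTest <- function(model, elety) {
  a <- alloDyn::atoms(model)
  as.matrix(a[a$elety == elety, c("x", "y", "z")])
}

# split a "chain:resno" residue id
parseKeysForTest <- function(res) {
  p <- strsplit(res, ":", fixed = TRUE)[[1]]
  list(chain = p[1], resno = as.integer(p[2]))
}
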