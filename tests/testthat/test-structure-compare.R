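# Structure I/O, Kabsch superposition, displacements, contacts, distances.

test_that("a hand-written PDB is echoed atom for atom", {
  path <- writeToyPDB(tempfile(fileext = ".pdb"))
  m <- readStructure(path)
  a <- atoms(m)
  expect_equal(nrow(a), 3)
  expect_equal(a$x, c(1.0, 2.5, 3.2), tolerance = 1e-3)
  expect_equal(a$elety, c("N", "CA", "C"))
  expect_equal(a$resno, c(1L, 1L, 1L))
})

test_that("PDB and mmCIF renderings of one model read back identically", {
  ref <- makeSyntheticTrimer(nRes = 5, withLigand = TRUE)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".cif")
  writeStructure(ref, p1); writeStructure(ref, p2)
  mp <- readStructure(p1); mc <- readStructure(p2)
  cols <- c("chain", "resno", "resid", "elety")
  expect_equal(atoms(mp)[, cols], atoms(mc)[, cols])
  expect_equal(atoms(mp)[, c("x", "y", "z")],
               atoms(mc)[, c("x", "y", "z")], tolerance = 1e-3)
  # and the echo matches the in-memory model
  expect_equal(atoms(mp)$x, atoms(ref)$x, tolerance = 1e-3)
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA  ALA A   2       5.000   0.000   0.000  1.00 10.00           C",
    "ATOM      4  CA  ALA A   3       5.000   4.000   0.000  1.00 10.00           C",
    "END"), path)
  m <- readStructure(path, altloc = "highest")
  a <- atoms(m)
  expect_equal(nrow(a), 3)
  expect_equal(a$x[a$resno == 1], 2.0)
  mf <- readStructure(path, altloc = "first")
  expect_equal(atoms(mf)$x[atoms(mf)$resno == 1], 1.0)
})

test_that("unparseable or missing files raise format errors", {
  expect_error(readStructure(tempfile()), "not found")
  bad <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_foo.bar", "1"), bad)
  expect_error(readStructure(bad), "_atom_site")
})

test_that("self-superposition and rigid-motion superposition give RMSD 0", {
  m <- makeSyntheticTrimer(nRes = 8)
  expect_equal(superpose(m, m)@rmsd, 0, tolerance = 1e-12)
  pair <- simulateStructurePair(m, translation = c(-4, 9, 2), seed = 8)
  expect_lt(superpose(pair$transformed, m)@rmsd, 1e-6)
})

test_that("Kabsch matches the quaternion oracle on perturbed pairs", {
  ref <- makeSyntheticTrimer(nRes = 25)   # 300 atoms
  for (seed in c(1, 2, 3)) {
    pair <- simulateStructurePair(ref, perturbSd = 0.5, seed = seed)
    sup <- superpose(pair$transformed, ref, selection = "all")
    xm <- as.matrix(atoms(pair$transformed)[, c("x", "y", "z")])
    xr <- as.matrix(atoms(ref)[, c("x", "y", "z")])
    oracle <- quaternionSuperpose(xm, xr)
    expect_lt(abs(sup@rmsd - oracle$rmsd), 1e-6)
    expect_equal(det(sup@rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition RMSD is symmetric in its arguments", {
  ref <- makeSyntheticTrimer(nRes = 10)
  for (seed in 1:5) {
    pair <- simulateStructurePair(ref, perturbSd = 0.8, seed = seed)
    ab <- superpose(pair$transformed, ref)@rmsd
    ba <- superpose(ref, pair$transformed)@rmsd
    expect_lt(abs(ab - ba), 1e-6)
  }
})

test_that("superposition errors on insufficient or collinear pairings", {
  m <- makeSyntheticTrimer(nRes = 8)
  a <- atoms(m)[1:8, ]
  a$x <- seq_len(8); a$y <- 0; a$z <- 0   # collinear line
  lin <- new("StructureModel", atoms = a, source = "synthetic")
  expect_error(superpose(lin, lin, selection = "all"), "collinear")
  two <- new("StructureModel", atoms = atoms(m)[1:2, ],
             source = "synthetic")
  expect_error(superpose(two, m, selection = "all"),
               "insufficient pairing")
})

test_that("chain mapping permutes trimer chains before pairing", {
  # jitter breaks the exact 3-fold symmetry, so relabeled chains no longer
  # superpose under identity pairing
  m <- makeSyntheticTrimer(nRes = 8, seed = 1, jitterSd = 0.4)
  a <- atoms(m)
  relabeled <- new("StructureModel",
                   atoms = transform(a, chain = c(A = "B", B = "C",
                                                  C = "A")[chain]),
                   source = "synthetic")
  expect_error(sup0 <- superpose(relabeled, m), NA)
  expect_gt(sup0@rmsd, 0.1)   # identity pairing misaligns the chains
  sup <- superpose(relabeled, m, chainMap = c(B = "A", C = "B", A = "C"))
  expect_lt(sup@rmsd, 1e-9)
})

test_that("single-atom displacement after superposition on the rest", {
  m <- makeSyntheticTrimer(nRes = 20)
  a <- atoms(m)
  i <- which(a$chain == "A" & a$resno == 5 & a$elety == "N")
  a$x[i] <- a$x[i] + 1.0
  moved <- new("StructureModel", atoms = a, source = "synthetic")
  expect_equal(atomDisplacement(m, m, superpose(m, m), "A:5:N"), 0)
  # superpose on C-alphas (unmoved): the planted +1 A offset is recovered
  sup <- superpose(moved, m, selection = "calpha")
  expect_equal(atomDisplacement(moved, m, sup, "A:5:N"), 1.0,
               tolerance = 1e-6)
  expect_error(atomDisplacement(moved, m, sup, "Z:99:XX"), "not found")
})

test_that("ligand contacts honour the cutoff exactly", {
  a <- data.frame(
    chain = c("L", "A", "A"), resno = c(500L, 1L, 2L),
    resid = c("TLA", "ALA", "ALA"), elety = c("O1", "CA", "CA"),
    element = c("O", "C", "C"), occ = 1,
    x = c(0, 3.9, 4.1), y = 0, z = 0)
  m <- new("StructureModel", atoms = a, source = "synthetic")
  expect_equal(ligandContacts(m, "TLA", cutoff = 4.0), "A:1")
  expect_equal(ligandContacts(m, "TLA", cutoff = 0.0), character(0))
  expect_error(ligandContacts(m, "XYZ"), "ligand not found")
})

test_that("interatomic distances: 3-4-5 triangle and self-distance", {
  a <- data.frame(chain = "A", resno = c(1L, 2L), resid = "GLY",
                  elety = "CA", element = "C", occ = 1,
                  x = c(0, 3), y = c(0, 4), z = 0)
  m <- new("StructureModel", atoms = a, source = "synthetic")
  expect_equal(atomDistance(m, "A:1:CA", "A:2:CA"), 5.0)
  expect_equal(atomDistance(m, "A:1:CA", "A:1:CA"), 0)
  expect_error(atomDistance(m, "A:1:CA", "A:9:CA"), "not found")
})

test_that("structural metrics are invariant under joint rigid motion", {
  m <- makeSyntheticTrimer(nRes = 10, withLigand = TRUE)
  pairA <- simulateStructurePair(m, perturbSd = 0.3, seed = 6)
  rmsd0 <- superpose(pairA$transformed, m)@rmsd
  R <- testRotation(1.1); tr <- c(15, -8, 3)
  moveModel <- function(mm) {
    aa <- atoms(mm)
    xyz <- sweep(as.matrix(aa[, c("x", "y", "z")]) %*% t(R), 2, tr, `+`)
    aa$x <- xyz[, 1]; aa$y <- xyz[, 2]; aa$z <- xyz[, 3]
    new("StructureModel", atoms = aa, source = "synthetic")
  }
  expect_equal(superpose(moveModel(pairA$transformed), moveModel(m))@rmsd,
               rmsd0, tolerance = 1e-9)
  expect_equal(ligandContacts(moveModel(m), "TLA", 4.0),
               ligandContacts(m, "TLA", 4.0))
})
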