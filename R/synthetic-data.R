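# Synthetic-data generators: every input class the pipeline consumes, with
# known ground truth. Fixtures encode statistical structure only, not
# force-field physics.

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Ground-truth mutual information of an isotropically correlated 3D pair
#'
#' For two 3-vector Gaussian displacement series whose Cartesian components
#' are pairwise correlated with the same Pearson `rho` (independently per
#' component), the mutual information is `-(3/2) * log(1 - rho^2)` nats.
#'
#' @param rho per-component Pearson correlation in `[-1, 1]`.
#' @return mutual information in nats (`Inf` at `|rho| = 1`).
#' @export
#' @examples
#' gaussianMutualInformation(0.8)   # 1.5325 nats
gaussianMutualInformation <- function(rho) {
  stopifnot(all(abs(rho) <= 1))
  -1.5 * log(1 - rho^2)
}

#' Simulate correlated per-residue displacement series
#'
#' Draws `nFrames` samples of `nResidues` 3-vector displacements whose
#' Cartesian components are mutually Gaussian with the requested
#' residue-residue correlation matrix, applied independently and identically
#' to each of the three components (isotropy). Under this construction the
#' generalized correlation coefficient of a pair equals `|rho|` exactly in
#' the large-sample limit, giving a closed-form target for estimator tests.
#'
#' @param nFrames number of frames (samples), >= 2.
#' @param nResidues number of residues.
#' @param correlation symmetric positive-semidefinite matrix with unit
#'   diagonal (`nResidues` x `nResidues`); default identity (independent
#'   residues).
#' @param sd per-component displacement standard deviation, Angstrom.
#' @param seed integer seed; equal seeds give bit-identical output.
#' @return a [DisplacementSeries-class]; its `trueMI` slot carries the
#'   closed-form pairwise mutual information for assertions.
#' @export
simulateCorrelatedTrajectory <- function(nFrames, nResidues,
                                         correlation = diag(nResidues),
                                         sd = 1, seed = 1) {
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != nResidues || ncol(correlation) != nResidues)
    stop("correlation must be ", nResidues, " x ", nResidues)
  if (max(abs(correlation - t(correlation))) > 1e-10)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("correlation matrix must be positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nResidues)

  samples <- withSeed(seed, {
    out <- array(0, dim = c(nFrames, nResidues, 3))
    for (comp in 1:3) {
      z <- matrix(stats::rnorm(nFrames * nResidues), nFrames, nResidues)
      x <- sd * (z %*% t(L))
      out[, , comp] <- sweep(x, 2, colMeans(x))  # displacements about mean
    }
    out
  })

  trueMI <- gaussianMutualInformation(pmin(abs(correlation), 1))
  diag(trueMI) <- NA_real_
  new("DisplacementSeries",
      samples = samples,
      labels = paste0("A:", seq_len(nResidues)),
      trueMI = trueMI)
}

#' Default relaxation delay schedules
#'
#' The longitudinal (T1) schedule spans 0-2500 ms with duplicate delays at
#' 20, 60 and 600 ms; the transverse (T2, CPMG) schedule spans 0-203 ms of
#' total relaxation delay with duplicates at 16.9, 33.9, 136 and 203 ms.
#'
#' @param kind "T1" or "T2".
#' @return list with `delays` and `replicateDelays`, both in seconds.
#' @export
relaxationDelaySchedule <- function(kind = c("T1", "T2")) {
  kind <- match.arg(kind)
  if (kind == "T1")
    list(delays = c(0, 20, 60, 100, 200, 600, 800, 1200, 1500, 2000,
                    2500) / 1000,
         replicateDelays = c(20, 60, 600) / 1000)
  else
    list(delays = c(0, 16.9, 33.9, 67.8, 136, 169, 203) / 1000,
         replicateDelays = c(16.9, 33.9, 136, 203) / 1000)
}

#' Simulate exponential relaxation decay curves
#'
#' Generates per-residue peak-height tables `I(t) = I0 * exp(-rate * t)`
#' with additive Gaussian noise on intensity, the error model implied by
#' least-squares exponential fitting of peak heights. Delays listed in
#' `replicateDelays` are measured twice (replicate ids 1 and 2), mirroring
#' duplicate relaxation delays used for uncertainty estimation.
#'
#' @param rates true decay rate(s), s^-1; recycled to `nResidues`.
#' @param nResidues number of residues.
#' @param delays delay schedule in seconds (non-empty, all >= 0).
#' @param replicateDelays subset of `delays` measured twice.
#' @param I0 initial intensity (arbitrary units).
#' @param noiseSd noise standard deviation as a fraction of `I0`.
#' @param seed integer seed.
#' @param kind "T1" or "T2" (labelling only).
#' @return a [RelaxationSeries-class] whose `trueRates` slot carries the
#'   generating rates.
#' @export
simulateDecayCurves <- function(rates, nResidues = length(rates),
                                delays = relaxationDelaySchedule("T1")$delays,
                                replicateDelays =
                                  relaxationDelaySchedule("T1")$replicateDelays,
                                I0 = 100, noiseSd = 0.02, seed = 1,
                                kind = c("T1", "T2")) {
  kind <- match.arg(kind)
  if (length(delays) == 0) stop("delays must be non-empty")
  if (any(delays < 0)) stop("delays must be non-negative")
  if (!all(replicateDelays %in% delays))
    stop("replicateDelays must be a subset of delays")
  rates <- rep_len(rates, nResidues)

  sched <- data.frame(delay_s = c(delays, replicateDelays),
                      replicate = c(rep(1L, length(delays)),
                                    rep(2L, length(replicateDelays))))
  records <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nResidues), function(i) {
      ideal <- I0 * exp(-rates[i] * sched$delay_s)
      data.frame(residue = i,
                 delay_s = sched$delay_s,
                 intensity = ideal + if (noiseSd > 0)
                   stats::rnorm(nrow(sched), 0, noiseSd * I0) else 0,
                 replicate = sched$replicate)
    }))
  })
  names(rates) <- as.character(seq_len(nResidues))
  new("RelaxationSeries", kind = kind, records = records, trueRates = rates,
      metadata = list(I0 = I0, noiseSd = noiseSd, seed = seed))
}

#' Plant waters inside and outside a solvent channel
#'
#' Builds a single- or multi-frame fixture with three upper-gate and three
#' lower-gate C-alpha positions plus water oxygens planted so that exactly
#' `nInside` satisfy the channel membership predicate (axial slab + radial
#' cutoff, see [channelMembership()]) and exactly `nOutside` violate it.
#' Planted positions are re-checked against the predicate at generation
#' time, so the fixture's labels are sound by construction.
#'
#' @param gateUpper,gateLower 3 x 3 matrices of gate C-alpha coordinates
#'   (one row per monomer), Angstrom; non-collinear.
#' @param nInside,nOutside number of waters to plant inside / outside.
#' @param radialMargin Angstrom added to the larger gate circumradius.
#' @param nFrames number of identical frames to emit.
#' @param seed integer seed.
#' @return list with `trajectory` (a [Trajectory-class] containing gate
#'   C-alphas on chains A/B/C and HOH waters), `channel` (the matching
#'   [ChannelDefinition-class]), and `inside` (logical ground truth per
#'   water).
#' @export
simulateChannelFrame <- function(gateUpper, gateLower, nInside = 5,
                                 nOutside = 3, radialMargin = 2,
                                 nFrames = 1, seed = 1) {
  gateUpper <- as.matrix(gateUpper); gateLower <- as.matrix(gateLower)
  geom <- channelGeometry(gateUpper, gateLower, radialMargin)  # validates

  waters <- withSeed(seed, {
    inside <- matrix(numeric(0), 0, 3)
    if (nInside > 0) {
      t <- stats::runif(nInside, 0.1, 0.9) * geom$length
      r <- stats::runif(nInside, 0, 0.8 * geom$radialCutoff)
      th <- stats::runif(nInside, 0, 2 * pi)
      inside <- t(vapply(seq_len(nInside), function(i) {
        geom$lowerCentroid + t[i] * geom$axis +
          r[i] * (cos(th[i]) * geom$perp1 + sin(th[i]) * geom$perp2)
      }, numeric(3)))
    }
    outside <- matrix(numeric(0), 0, 3)
    if (nOutside > 0) {
      # alternate axial overshoot and radial overshoot
      outside <- t(vapply(seq_len(nOutside), function(i) {
        if (i %% 2 == 1) {
          geom$upperCentroid + (1 + stats::runif(1, 1, 5)) * geom$axis
        } else {
          th <- stats::runif(1, 0, 2 * pi)
          geom$lowerCentroid + stats::runif(1, 0.2, 0.8) * geom$length *
            geom$axis +
            (geom$radialCutoff + stats::runif(1, 0.5, 3)) *
            (cos(th) * geom$perp1 + sin(th) * geom$perp2)
        }
      }, numeric(3)))
    }
    rbind(inside, outside)
  })
  insideTruth <- rep(c(TRUE, FALSE), c(nInside, nOutside))

  # fixture soundness: labels must agree with the membership predicate
  if (nrow(waters) > 0) {
    got <- channelMembership(waters, gateUpper, gateLower, radialMargin)
    stopifnot(identical(got, insideTruth))
  }

  gates <- data.frame(
    chain = rep(c("A", "B", "C"), 2),
    resno = rep(c(100L, 42L), each = 3),
    resid = rep(c("PHE", "ARG"), each = 3),
    elety = "CA", element = "C", occ = 1,
    x = c(gateUpper[, 1], gateLower[, 1]),
    y = c(gateUpper[, 2], gateLower[, 2]),
    z = c(gateUpper[, 3], gateLower[, 3]))
  wat <- if (nrow(waters) > 0) data.frame(
    chain = "W", resno = 200L + seq_len(nrow(waters)), resid = "HOH",
    elety = "O", element = "O", occ = 1,
    x = waters[, 1], y = waters[, 2], z = waters[, 3]) else NULL
  top <- new("StructureModel", atoms = rbind(gates, wat),
             source = "synthetic")
  xyz <- as.matrix(top@atoms[, c("x", "y", "z")])
  coords <- array(rep(t(xyz), nFrames),
                  dim = c(3, nrow(xyz), nFrames))
  coords <- aperm(coords, c(3, 2, 1))
  channel <- new("ChannelDefinition",
                 upperGate = c("A:100", "B:100", "C:100"),
                 lowerGate = c("A:42", "B:42", "C:42"),
                 radialMargin = radialMargin)
  list(trajectory = new("Trajectory", coords = coords, topology = top),
       channel = channel, inside = insideTruth)
}

#' Build a toy trimeric structure
#'
#' A synthetic stand-in for a homotrimeric tautomerase: three identical
#' chains (A, B, C) of backbone atoms (N, CA, C, O) arranged on a gentle
#' helix and related by 120-degree rotations about the z axis, optionally
#' with a central tartrate-like ligand (residue name TLA, chain L) and a few
#' waters. Purely geometric; used for structural-metric tests.
#'
#' @param nRes residues per chain.
#' @param withLigand add a 4-atom central ligand (resid TLA).
#' @param radius placement radius of the chain backbone, Angstrom.
#' @param seed integer seed for small coordinate jitter (0 jitter if NULL).
#' @param jitterSd per-atom Gaussian jitter, Angstrom.
#' @return a [StructureModel-class].
#' @export
makeSyntheticTrimer <- function(nRes = 30, withLigand = FALSE, radius = 12,
                                seed = NULL, jitterSd = 0) {
  oneChain <- function(chain, rot) {
    t <- seq(0, 3 * pi, length.out = nRes)
    ca <- cbind(radius * cos(t), radius * sin(t), 2.5 * t)
    rows <- lapply(seq_len(nRes), function(i) {
      base <- ca[i, ]
      data.frame(
        chain = chain, resno = i,
        resid = c("ALA", "GLY", "SER", "VAL", "LEU")[(i %% 5) + 1],
        elety = c("N", "CA", "C", "O"),
        element = c("N", "C", "C", "O"), occ = 1,
        x = base[1] + c(-1.2, 0, 1.2, 1.8),
        y = base[2] + c(0.5, 0, 0.5, 1.4),
        z = base[3] + c(-0.3, 0, 0.3, -0.4))
    })
    a <- do.call(rbind, rows)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a
  }
  rotz <- function(th) matrix(c(cos(th), sin(th), 0,
                                -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a <- rbind(oneChain("A", diag(3)),
             oneChain("B", rotz(2 * pi / 3)),
             oneChain("C", rotz(4 * pi / 3)))
  if (withLigand) {
    # ligand sits 3.2 A off a mid-chain C-alpha so it has a contact shell
    mid <- a[a$chain == "A" & a$resno == max(1, nRes %/% 2) &
               a$elety == "CA", ]
    ctr <- c(mid$x, mid$y, mid$z) + c(3.2, 0, 0)
    lig <- data.frame(
      chain = "L", resno = 500L, resid = "TLA",
      elety = c("O1", "O2", "C1", "C2"),
      element = c("O", "O", "C", "C"), occ = 1,
      x = ctr[1] + c(0, 1.2, 0.6, -0.6),
      y = ctr[2] + c(0, 0.4, -0.8, 0.8),
      z = ctr[3] + c(0, 0.5, -0.5, 0.2))
    a <- rbind(a, lig)
  }
  if (!is.null(seed) && jitterSd > 0) {
    a[, c("x", "y", "z")] <- withSeed(seed, {
      a[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(a), 0, jitterSd), nrow(a), 3)
    })
  }
  new("StructureModel", atoms = a, source = "synthetic")
}

#' Simulate a rigidly transformed, optionally perturbed structure pair
#'
#' Applies a rigid rotation and translation (random proper rotation if not
#' supplied) plus optional per-atom Gaussian perturbation to a reference
#' structure. With zero perturbation the optimal superposition RMSD of the
#' pair is 0 to numerical tolerance.
#'
#' @param reference a [StructureModel-class].
#' @param rotation 3x3 proper rotation or NULL (random).
#' @param translation length-3 vector, Angstrom.
#' @param perturbSd per-atom isotropic Gaussian perturbation sd, Angstrom.
#' @param seed integer seed.
#' @return list with `reference`, `transformed` ([StructureModel-class]),
#'   `rotation`, `translation`, `perturbSd`.
#' @export
simulateStructurePair <- function(reference, rotation = NULL,
                                  translation = c(5, -3, 8),
                                  perturbSd = 0, seed = 1) {
  withSeed(seed, {
    if (is.null(rotation)) rotation <- randomRotation()
    a <- atoms(reference)
    xyz <- applyTransform(as.matrix(a[, c("x", "y", "z")]),
                          rotation, translation)
    if (perturbSd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, perturbSd),
                          nrow(xyz), 3)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    list(reference = reference,
         transformed = new("StructureModel", atoms = a,
                           source = "synthetic"),
         rotation = rotation, translation = translation,
         perturbSd = perturbSd)
  })
}
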