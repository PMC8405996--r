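# Solvent-channel analysis: gated water counting, channel-expansion metric,
# and a Gaussian-kernel occupancy-density grid.

# resolve channel geometry from the two gate C-alpha triangles: axis through
# the centroids, capped slab, radial cutoff = max circumradius + margin
channelGeometry <- function(gateUpper, gateLower, radialMargin = 2) {
  gateUpper <- as.matrix(gateUpper); gateLower <- as.matrix(gateLower)
  stopifnot(all(dim(gateUpper) == c(3, 3)), all(dim(gateLower) == c(3, 3)))
  rUp <- circumradius(gateUpper)       # errors on collinear gates
  rLo <- circumradius(gateLower)
  cu <- colMeans(gateUpper); cl <- colMeans(gateLower)
  ax <- cu - cl
  len <- sqrt(sum(ax^2))
  if (len < 1e-9) stop("degenerate geometry: gate centroids coincide")
  ax <- ax / len
  # orthonormal frame completing the axis
  seed <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- seed - sum(seed * ax) * ax
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- crossprodVec(ax, p1)
  list(axis = ax, lowerCentroid = cl, upperCentroid = cu, length = len,
       radialCutoff = max(rUp, rLo) + radialMargin,
       perp1 = p1, perp2 = p2)
}

#' Channel membership of water positions
#'
#' A water belongs to the channel iff its projection onto the channel axis
#' (the line through the lower- and upper-gate triangle centroids) lies
#' between the two centroid projections, and its distance from the axis is
#' at most the larger gate circumradius plus `radialMargin`
#' (`radialMargin = Inf` gives a slab-only test).
#'
#' @param positions numeric n x 3 matrix (or length-3 vector) of water
#'   oxygen positions, Angstrom.
#' @param gateUpper,gateLower 3 x 3 matrices of gate C-alpha coordinates.
#' @param radialMargin Angstrom.
#' @return logical vector, one per position.
#' @export
channelMembership <- function(positions, gateUpper, gateLower,
                              radialMargin = 2) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  geom <- channelGeometry(gateUpper, gateLower, radialMargin)
  rel <- sweep(positions, 2, geom$lowerCentroid)
  t <- as.numeric(rel %*% geom$axis)
  radial2 <- rowSums(rel^2) - t^2
  axial <- t >= 0 & t <= geom$length
  if (is.infinite(geom$radialCutoff)) return(axial)
  axial & radial2 <= geom$radialCutoff^2 + 1e-12
}

# resolve "chain:resno" gate residue ids to C-alpha coordinates in a frame
gateCoords <- function(atomTable, frameXYZ, gateIds) {
  k <- parseKeys(gateIds)
  idx <- vapply(seq_len(nrow(k)), function(i) {
    w <- which(atomTable$chain == k$chain[i] &
               atomTable$resno == k$resno[i] & atomTable$elety == "CA")
    if (length(w) == 0) stop("gate residue not found: ", gateIds[i])
    w[1]
  }, integer(1))
  frameXYZ[idx, , drop = FALSE]
}

#' Count channel waters per frame
#'
#' Applies the channel membership predicate to every water oxygen in every
#' frame of the analysis window, with gate coordinates re-resolved per frame
#' so that gate motion is followed.
#'
#' @param traj a [Trajectory-class] whose topology names waters by residue
#'   name (HOH/WAT/TIP3, configurable on the channel definition).
#' @param channel a [ChannelDefinition-class].
#' @param window integer frame indices (default all).
#' @return a [WaterCount-class]. If the topology contains no waters a
#'   zero-count result is returned with a warning.
#' @export
countChannelWaters <- function(traj, channel, window = NULL) {
  a <- atoms(traj)
  if (is.null(window)) window <- seq_len(nFrames(traj))
  wat <- which(a$resid %in% channel@waterNames & a$element == "O")
  meta <- list(radialMargin = channel@radialMargin,
               upperGate = channel@upperGate,
               lowerGate = channel@lowerGate,
               oxygenOnly = TRUE, window = range(window))
  if (length(wat) == 0) {
    warning("no waters in topology; returning zero counts")
    return(new("WaterCount", perFrame = integer(length(window)),
               mean = 0, nFrames = length(window), metadata = meta))
  }
  counts <- vapply(window, function(f) {
    xyz <- traj@coords[f, , ]
    up <- gateCoords(a, xyz, channel@upperGate)
    lo <- gateCoords(a, xyz, channel@lowerGate)
    sum(channelMembership(xyz[wat, , drop = FALSE], up, lo,
                          channel@radialMargin))
  }, integer(1))
  new("WaterCount", perFrame = counts, mean = mean(counts),
      nFrames = length(window), metadata = meta)
}

#' Gate-aperture metric and channel expansion between two trajectories
#'
#' The aperture of a gate is the mean of the three pairwise distances among
#' the time-averaged gate C-alpha positions; being built from internal
#' distances it is invariant to rigid motion of the trajectory. The
#' expansion between two systems is the signed difference
#' `aperture(b) - aperture(a)`.
#'
#' @param trajA,trajB [Trajectory-class] objects (e.g. two protein
#'   variants).
#' @param gate character vector of three gate residue ids `"chain:resno"`
#'   (present in both topologies).
#' @param window integer frame indices (default all), applied to both.
#' @return list with `apertureA`, `apertureB` and `expansion`, Angstrom.
#' @export
channelExpansion <- function(trajA, trajB, gate, window = NULL) {
  aperture <- function(traj) {
    a <- atoms(traj)
    w <- if (is.null(window)) seq_len(nFrames(traj)) else window
    pos <- Reduce(`+`, lapply(w, function(f)
      gateCoords(a, traj@coords[f, , ], gate))) / length(w)
    mean(c(sqrt(sum((pos[1, ] - pos[2, ])^2)),
           sqrt(sum((pos[2, ] - pos[3, ])^2)),
           sqrt(sum((pos[3, ] - pos[1, ])^2))))
  }
  apA <- aperture(trajA); apB <- aperture(trajB)
  list(apertureA = apA, apertureB = apB, expansion = apB - apA)
}

#' Accumulate water observations into an occupancy-density grid
#'
#' Deposits a normalized 3D Gaussian kernel at each observed water-oxygen
#' position onto a regular grid, an analog of building a density map from
#' channel waters pooled over all frames; persistently occupied hydration
#' sites then stand out as high-density voxels isolated by a sigma-level
#' threshold ([thresholdOccupancy()]).
#'
#' @param positions n x 3 matrix of water-oxygen observations pooled over
#'   frames, Angstrom.
#' @param spacing voxel edge, Angstrom (> 0).
#' @param kernelWidth Gaussian sigma, Angstrom; a 1.0 A kernel approximates
#'   a 1 A resolution map.
#' @param padding grid padding beyond the data extent, Angstrom (default
#'   `5 * kernelWidth` so kernels are fully contained).
#' @return an [OccupancyGrid-class]; total density times voxel volume equals
#'   the number of observations (within kernel-truncation error).
#' @export
buildOccupancyGrid <- function(positions, spacing = 0.5, kernelWidth = 1.0,
                               padding = 5 * kernelWidth) {
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) stop("need at least one observation")
  lo <- apply(positions, 2, min) - padding
  hi <- apply(positions, 2, max) + padding
  nvox <- pmax(ceiling((hi - lo) / spacing) + 1, 2)
  axes <- lapply(1:3, function(d) lo[d] + (seq_len(nvox[d]) - 1) * spacing)
  dens <- array(0, dim = nvox)
  norm <- (2 * pi * kernelWidth^2)^(-1.5)
  reach <- ceiling(5 * kernelWidth / spacing)
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    ctr <- round((p - lo) / spacing) + 1
    rng <- lapply(1:3, function(d)
      max(1, ctr[d] - reach):min(nvox[d], ctr[d] + reach))
    gx <- exp(-(axes[[1]][rng[[1]]] - p[1])^2 / (2 * kernelWidth^2))
    gy <- exp(-(axes[[2]][rng[[2]]] - p[2])^2 / (2 * kernelWidth^2))
    gz <- exp(-(axes[[3]][rng[[3]]] - p[3])^2 / (2 * kernelWidth^2))
    dens[rng[[1]], rng[[2]], rng[[3]]] <-
      dens[rng[[1]], rng[[2]], rng[[3]]] + norm * outer(outer(gx, gy), gz)
  }
  new("OccupancyGrid", density = dens, origin = lo, spacing = spacing,
      kernelWidth = kernelWidth, nObservations = nrow(positions))
}

#' Isolate persistently occupied voxels at a sigma level
#'
#' Keeps voxels whose density is at least `mean + sigmaLevel * sd`, both
#' statistics taken over the nonzero voxels of the grid. Raising the level
#' monotonically shrinks the surviving set.
#'
#' @param grid an [OccupancyGrid-class].
#' @param sigmaLevel threshold multiplier (e.g. 15 for only the most
#'   persistent hydration sites).
#' @return data.frame of surviving voxels: `x`, `y`, `z` (voxel centres,
#'   Angstrom) and `density`.
#' @export
thresholdOccupancy <- function(grid, sigmaLevel = 15) {
  d <- grid@density
  nz <- d[d > 0]
  if (length(nz) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      density = numeric(0)))
  thr <- mean(nz) + sigmaLevel * stats::sd(nz)
  idx <- which(d >= thr, arr.ind = TRUE)
  data.frame(x = grid@origin[1] + (idx[, 1] - 1) * grid@spacing,
             y = grid@origin[2] + (idx[, 2] - 1) * grid@spacing,
             z = grid@origin[3] + (idx[, 3] - 1) * grid@spacing,
             density = d[idx])
}
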