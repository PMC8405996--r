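# Mutual-information-based generalized correlation of per-residue
# displacement vectors from aligned trajectory frames.

#' Read a multi-model PDB trajectory
#'
#' @param path multi-model PDB file (MODEL/ENDMDL records; single-model
#'   files give a 1-frame trajectory).
#' @return a [Trajectory-class].
#' @export
readTrajectoryPDB <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- readStructure(path)           # frame-1 topology, altloc-resolved
  nAtom <- nrow(atoms(top))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nAtom)
    stop("frame/topology atom-count mismatch: frames have ",
         ncol(xyz) / 3, " atoms, topology has ", nAtom)
  coords <- array(NA_real_, dim = c(nrow(xyz), nAtom, 3))
  for (f in seq_len(nrow(xyz)))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new("Trajectory", coords = coords, topology = top)
}

#' Read a DCD trajectory with a PDB topology
#'
#' @param dcd DCD coordinate file.
#' @param topology PDB file labelling the atoms.
#' @return a [Trajectory-class].
#' @export
readTrajectoryDCD <- function(dcd, topology) {
  top <- readStructure(topology)
  xyz <- bio3d::read.dcd(dcd, verbose = FALSE)
  nAtom <- nrow(atoms(top))
  if (ncol(xyz) != 3 * nAtom)
    stop("frame/topology atom-count mismatch")
  coords <- array(NA_real_, dim = c(nrow(xyz), nAtom, 3))
  for (f in seq_len(nrow(xyz)))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new("Trajectory", coords = coords, topology = top)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  a <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    a$x <- traj@coords[f, , 1]
    a$y <- traj@coords[f, , 2]
    a$z <- traj@coords[f, , 3]
    writeLines(c(sprintf("MODEL     %4d", f), pdbAtomLines(a), "ENDMDL"),
               con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract aligned per-residue displacement series from a trajectory
#'
#' Frames in the analysis window are least-squares superposed (C-alpha by
#' default) onto the window-average structure, and each selected atom's
#' displacement is its position minus its mean position. The alignment
#' reference is refined once: frames are first aligned to the initial frame,
#' averaged, then re-aligned to that average.
#'
#' @param traj a [Trajectory-class].
#' @param selection atom selection used both for alignment and output;
#'   "calpha" (default), "heavy", "backbone", "all".
#' @param window integer frame indices to analyse (default all frames).
#' @return a [DisplacementSeries-class] labelled `"chain:resno"`.
#' @export
extractDisplacements <- function(traj, selection = "calpha",
                                 window = NULL) {
  a <- atoms(traj)
  sel <- which(selectAtoms(a, selection))
  if (length(sel) == 0) stop("selection matches no atoms")
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (length(window) < 2) stop("need at least 2 frames in the window")
  co <- traj@coords[window, sel, , drop = FALSE]
  nf <- dim(co)[1]

  alignTo <- function(ref) {
    out <- co
    for (f in seq_len(nf)) {
      fit <- kabsch(co[f, , ], ref)
      out[f, , ] <- applyTransform(co[f, , ], fit$rotation,
                                   fit$translation)
    }
    out
  }
  aligned <- alignTo(co[1, , ])
  refMean <- apply(aligned, c(2, 3), mean)
  aligned <- alignTo(refMean)
  meanPos <- apply(aligned, c(2, 3), mean)
  disp <- sweep(aligned, c(2, 3), meanPos)

  new("DisplacementSeries", samples = disp,
      labels = paste(a$chain[sel], a$resno[sel], sep = ":"))
}

#' Estimate mutual information between two displacement series
#'
#' Default estimator: Kraskov-type k-nearest-neighbour (k = 4) on the 3D
#' marginal / 6D joint displacement spaces, max-norm. A fixed-width
#' histogram (binned Shannon entropy) estimator is available as a
#' cross-check. Estimates are clamped at 0 from below; numerically identical
#' inputs are capped at `iMax` nats and flagged via the
#' `"degenerate"` attribute.
#'
#' @param x,y numeric matrices `[n, d]` of displacement samples (equal `n`).
#' @param method "knn" (default) or "histogram".
#' @param k neighbour order for the knn estimator.
#' @param bins bin count per dimension for the histogram estimator.
#' @param maxSamples subsample cap: when `n` exceeds this, an evenly strided
#'   subsample of this size is analysed (documented estimator parameter,
#'   keeps the O(n^2) scan tractable).
#' @param minSamples minimum sample count (default 1000; generator examples
#'   below that size should pass `minSamples` explicitly).
#' @param iMax cap for degenerate (identical-input) pairs, nats.
#' @return mutual information in nats (attribute `degenerate` TRUE if the
#'   cap was applied).
#' @export
mutualInformation <- function(x, y, method = c("knn", "histogram"), k = 4,
                              bins = 12, maxSamples = 10000,
                              minSamples = 1000, iMax = 20) {
  method <- match.arg(method)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y))
    stop("x and y must have equal sample counts")
  n <- nrow(x)
  if (n < minSamples)
    stop("undersampled: ", n, " samples < minimum ", minSamples)
  if (n > maxSamples) {
    idx <- round(seq(1, n, length.out = maxSamples))
    x <- x[idx, , drop = FALSE]; y <- y[idx, , drop = FALSE]
    n <- length(idx)
  }
  if (max(abs(x - y)) == 0) {
    out <- iMax
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mi <- if (method == "knn") {
    .ksg_mi(x, y, as.integer(k))
  } else {
    histogramMI(x, y, bins)
  }
  out <- min(max(mi, 0), iMax)
  attr(out, "degenerate") <- FALSE
  out
}

# fixed-width histogram MI: bin each dimension over its range; bin-width
# entropy corrections cancel in Hx + Hy - Hxy
histogramMI <- function(x, y, bins) {
  codes <- function(m) {
    cc <- rep(0, nrow(m))
    for (j in seq_len(ncol(m))) {
      r <- range(m[, j])
      w <- if (diff(r) > 0) diff(r) else 1
      b <- pmin(floor((m[, j] - r[1]) / w * bins), bins - 1)
      cc <- cc * bins + b
    }
    cc
  }
  ent <- function(cc) {
    p <- tabulate(match(cc, unique(cc)))
    p <- p / sum(p)
    -sum(p * log(p))
  }
  cx <- codes(x); cy <- codes(y)
  ent(cx) + ent(cy) - ent(paste(cx, cy))
}

#' Generalized correlation coefficient from mutual information
#'
#' Maps mutual information of two 3-vector displacement series to a
#' Pearson-like coefficient: `r = sqrt(1 - exp(-(2/3) * mi))`, strictly
#' increasing from 0 at independence towards 1. For Gaussian displacements
#' with isotropic per-component correlation `rho`, `r` recovers `|rho|`
#' exactly.
#'
#' @param mi mutual information, nats (>= 0; clamping happens upstream).
#' @param dim dimensionality of each displacement vector (3 for Cartesian
#'   displacements, giving the `2/3` exponent factor).
#' @return coefficient in `[0, 1)`.
#' @export
#' @examples
#' generalizedCorrelation(gaussianMutualInformation(0.8))  # 0.8
generalizedCorrelation <- function(mi, dim = 3) {
  if (any(mi < 0)) stop("mi must be >= 0 (clamp upstream)")
  sqrt(1 - exp(-(2 / dim) * mi))
}

#' Pairwise mutual information and generalized correlation matrices
#'
#' Runs the pair estimator over all residue pairs of a displacement series.
#' The diagonal of the generalized correlation matrix is set to 1 by
#' convention (self-correlation is not estimable by the pair estimator);
#' the diagonal of the mutual information matrix is 0.
#'
#' @param series a [DisplacementSeries-class].
#' @param method,k,maxSamples,minSamples,iMax passed to
#'   [mutualInformation()].
#' @param window optional integer frame indices restricting the analysis.
#' @return a [CorrelationResult-class] with matrices labelled by residue.
#' @export
correlationMatrix <- function(series, method = "knn", k = 4,
                              maxSamples = 10000, minSamples = 1000,
                              iMax = 20, window = NULL) {
  nR <- dim(series@samples)[2]
  if (nR < 2) stop("need at least 2 residues")
  if (is.null(window)) window <- seq_len(dim(series@samples)[1])
  mi <- matrix(0, nR, nR, dimnames = list(series@labels, series@labels))
  deg <- matrix(FALSE, nR, nR, dimnames = dimnames(mi))
  for (i in seq_len(nR - 1)) {
    xi <- series@samples[window, i, ]
    for (j in (i + 1):nR) {
      est <- tryCatch(
        mutualInformation(xi, series@samples[window, j, ], method = method,
                          k = k, maxSamples = maxSamples,
                          minSamples = minSamples, iMax = iMax),
        error = function(e)
          stop("pair (", series@labels[i], ", ", series@labels[j], "): ",
               conditionMessage(e)))
      mi[i, j] <- mi[j, i] <- as.numeric(est)
      deg[i, j] <- deg[j, i] <- isTRUE(attr(est, "degenerate"))
    }
  }
  g <- generalizedCorrelation(mi)
  diag(g) <- 1
  new("CorrelationResult", mi = mi, gcorr = g, degenerate = deg,
      method = list(method = method, k = k, maxSamples = maxSamples,
                    iMax = iMax, nFrames = length(window)))
}

#' Monomer-block view of a correlation matrix
#'
#' @param result a [CorrelationResult-class] labelled `"chain:resno"`.
#' @param chainA,chainB chain ids; equal chains give an intra-monomer block.
#' @return the gcorr submatrix for residues of `chainA` x `chainB`.
#' @export
monomerBlock <- function(result, chainA, chainB = chainA) {
  ch <- sub(":.*$", "", rownames(result@gcorr))
  result@gcorr[ch == chainA, ch == chainB, drop = FALSE]
}

#' Write correlation matrices to CSV
#'
#' @param result a [CorrelationResult-class].
#' @param prefix output path prefix; writes `<prefix>_mi.csv` and
#'   `<prefix>_gcorr.csv` with residue labels.
#' @return character vector of the two paths, invisibly.
#' @export
writeCorrelationCSV <- function(result, prefix) {
  p1 <- paste0(prefix, "_mi.csv"); p2 <- paste0(prefix, "_gcorr.csv")
  utils::write.csv(result@mi, p1)
  utils::write.csv(result@gcorr, p2)
  invisible(c(p1, p2))
}
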