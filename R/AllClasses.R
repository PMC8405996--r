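#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib alloDyn, .registration = TRUE
NULL

#' StructureModel: labeled atomic coordinates
#'
#' Container for a crystal structure or a trajectory topology: one row per
#' atom with chain, residue number, residue name, atom name, element,
#' occupancy and Cartesian coordinates in Angstrom.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `occ`, `x`, `y`, `z` (coordinates in Angstrom).
#' @slot source character label (file path, accession, or "synthetic").
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", source = "character"),
  prototype(source = NA_character_)
)

setValidity("StructureModel", function(object) {
  need <- c("chain", "resno", "resid", "elety", "element", "occ",
            "x", "y", "z")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss) > 0)
    return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 0 && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  key <- paste(object@atoms$chain, object@atoms$resno, object@atoms$elety)
  if (anyDuplicated(key))
    return("duplicate (chain, resno, atom name) keys after altloc resolution")
  TRUE
})

#' Trajectory: multi-frame coordinates plus topology
#'
#' @slot coords numeric array `[n_frames, n_atoms, 3]`, Angstrom.
#' @slot topology a [StructureModel-class] labelling the atoms.
#' @export
setClass("Trajectory",
  representation(coords = "array", topology = "StructureModel")
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be an [n_frames, n_atoms, 3] array")
  if (d[2] != nrow(object@topology@atoms))
    return("coords atom dimension does not match topology atom count")
  TRUE
})

#' DisplacementSeries: per-residue displacement vectors from aligned frames
#'
#' Per-frame 3-vector displacements of selected atoms (typically C-alpha,
#' one per residue) about their mean position after least-squares alignment
#' of the trajectory.
#'
#' @slot samples numeric array `[n_frames, n_residues, 3]`, Angstrom.
#' @slot labels character residue identifiers, `"chain:resno"`.
#' @slot trueMI optional symmetric matrix of ground-truth mutual information
#'   (nats) carried by synthetic generators for test assertions; 0 x 0 when
#'   unknown.
#' @export
setClass("DisplacementSeries",
  representation(samples = "array", labels = "character", trueMI = "matrix"),
  prototype(trueMI = matrix(numeric(0), 0, 0))
)

setValidity("DisplacementSeries", function(object) {
  d <- dim(object@samples)
  if (length(d) != 3 || d[3] != 3)
    return("samples must be an [n_frames, n_residues, 3] array")
  if (d[1] < 2) return("need at least 2 frames")
  if (length(object@labels) != d[2])
    return("labels length must equal the residue dimension")
  TRUE
})

#' CorrelationResult: mutual information and generalized correlation matrices
#'
#' @slot mi symmetric matrix of pairwise mutual information, nats.
#' @slot gcorr symmetric matrix of generalized correlation coefficients in
#'   `[0, 1]`; diagonal fixed at 1 by convention.
#' @slot degenerate logical matrix flagging pairs capped at the configured
#'   maximum mutual information (numerically identical series).
#' @slot method list of estimator metadata (method, k, maxSamples, seed).
#' @export
setClass("CorrelationResult",
  representation(mi = "matrix", gcorr = "matrix", degenerate = "matrix",
                 method = "list")
)

setValidity("CorrelationResult", function(object) {
  if (!isTRUE(all.equal(object@mi, t(object@mi))))
    return("mi matrix must be symmetric")
  if (any(object@mi < 0)) return("mi must be non-negative (clamped)")
  if (any(object@gcorr < 0 | object@gcorr > 1))
    return("gcorr must lie in [0, 1]")
  TRUE
})

#' ChannelDefinition: gating residues bounding the trimer solvent channel
#'
#' The channel mouth at either end is defined by one gating residue per
#' monomer (three residues per gate); membership of a water is decided
#' against the axis through the two gate-triangle centroids.
#'
#' @slot upperGate character vector of three residue ids `"chain:resno"`
#'   (Tyr99/Phe100 role).
#' @slot lowerGate character vector of three residue ids (Val42/Arg42 role).
#' @slot radialMargin numeric, Angstrom added to the larger gate circumradius
#'   for the radial cutoff; `Inf` gives a slab-only (no radial bound) mode.
#' @slot waterNames character residue names identifying waters.
#' @export
setClass("ChannelDefinition",
  representation(upperGate = "character", lowerGate = "character",
                 radialMargin = "numeric", waterNames = "character"),
  prototype(radialMargin = 2.0, waterNames = c("HOH", "WAT", "TIP3"))
)

setValidity("ChannelDefinition", function(object) {
  if (length(object@upperGate) != 3 || length(object@lowerGate) != 3)
    return("each gate needs exactly three residue identifiers")
  if (length(intersect(object@upperGate, object@lowerGate)) > 0)
    return("upper and lower gates must be disjoint residue sets")
  if (object@radialMargin < 0) return("radialMargin must be >= 0")
  TRUE
})

#' WaterCount: per-frame channel water counts
#'
#' @slot perFrame integer vector of per-frame counts.
#' @slot mean numeric, arithmetic mean over the analysed frames.
#' @slot nFrames integer, number of frames used.
#' @slot metadata list (gate geometry, radial cutoff, margin, window).
#' @export
setClass("WaterCount",
  representation(perFrame = "integer", mean = "numeric", nFrames = "integer",
                 metadata = "list")
)

setValidity("WaterCount", function(object) {
  if (any(object@perFrame < 0)) return("counts must be non-negative")
  if (length(object@perFrame) > 0 &&
      !isTRUE(all.equal(object@mean, mean(object@perFrame))))
    return("mean must equal the arithmetic mean of perFrame")
  TRUE
})

#' OccupancyGrid: voxelized water occupancy density
#'
#' Gaussian-kernel deposition of water-oxygen observations onto a regular
#' 3D grid; a sigma-level threshold over nonzero voxels isolates persistently
#' occupied hydration sites.
#'
#' @slot density numeric 3D array of accumulated density.
#' @slot origin numeric 3-vector, Angstrom (centre of the first voxel).
#' @slot spacing numeric, Angstrom.
#' @slot kernelWidth numeric, Gaussian sigma in Angstrom.
#' @slot nObservations integer, number of deposited water observations.
#' @export
setClass("OccupancyGrid",
  representation(density = "array", origin = "numeric", spacing = "numeric",
                 kernelWidth = "numeric", nObservations = "integer")
)

setValidity("OccupancyGrid", function(object) {
  if (object@spacing <= 0) return("spacing must be positive")
  if (any(object@density < 0)) return("density must be non-negative")
  TRUE
})

#' RelaxationSeries: per-residue relaxation decay records
#'
#' Peak-height series per residue per relaxation delay for T1/T2 experiments,
#' or saturated/reference peak-height pairs for the heteronuclear NOE.
#'
#' @slot kind one of "T1", "T2", "NOE".
#' @slot records data.frame. For T1/T2: columns `residue`, `delay_s`,
#'   `intensity`, `replicate` (replicate id, 1 for the primary measurement).
#'   For NOE: columns `residue`, `saturated`, `reference`.
#' @slot trueRates optional named numeric vector of ground-truth rates
#'   (s^-1) carried by synthetic generators.
#' @slot metadata list (recycle delay s, CPMG spacing ms, source).
#' @export
setClass("RelaxationSeries",
  representation(kind = "character", records = "data.frame",
                 trueRates = "numeric", metadata = "list"),
  prototype(trueRates = numeric(0), metadata = list())
)

setValidity("RelaxationSeries", function(object) {
  if (!object@kind %in% c("T1", "T2", "NOE"))
    return("kind must be one of T1, T2, NOE")
  if (object@kind %in% c("T1", "T2")) {
    need <- c("residue", "delay_s", "intensity", "replicate")
    if (!all(need %in% names(object@records)))
      return(paste("records needs columns:", paste(need, collapse = ", ")))
    if (any(object@records$delay_s < 0)) return("delays must be >= 0")
  } else {
    need <- c("residue", "saturated", "reference")
    if (!all(need %in% names(object@records)))
      return(paste("records needs columns:", paste(need, collapse = ", ")))
  }
  TRUE
})

#' OutlierReport: trimmed-mean / 1.5-sigma outlier calls on residue profiles
#'
#' @slot residue character or integer residue identifiers.
#' @slot deviation numeric per-residue deviation from the reference.
#' @slot trimmedMean numeric, 10 percent trimmed mean of the deviations
#'   (5 percent per tail).
#' @slot sigma numeric, standard deviation of the untrimmed deviations.
#' @slot flagged logical, `abs(deviation - trimmedMean) > nSigma * sigma`.
#' @slot rho numeric, Spearman rank correlation over all paired residues.
#' @slot nSigma numeric threshold multiplier (default 1.5).
#' @export
setClass("OutlierReport",
  representation(residue = "character", deviation = "numeric",
                 trimmedMean = "numeric", sigma = "numeric",
                 flagged = "logical", rho = "numeric", nSigma = "numeric")
)

setValidity("OutlierReport", function(object) {
  n <- length(object@residue)
  if (length(object@deviation) != n || length(object@flagged) != n)
    return("residue, deviation and flagged must have equal length")
  if (!is.na(object@rho) && (object@rho < -1 || object@rho > 1))
    return("rho must lie in [-1, 1]")
  TRUE
})

#' SuperpositionResult: optimal rigid-body alignment of paired atoms
#'
#' @slot rotation 3x3 proper rotation matrix (determinant +1).
#' @slot translation numeric 3-vector, Angstrom. The transform maps a mobile
#'   coordinate row-vector v to `v %*% t(rotation) + translation`.
#' @slot rmsd numeric, minimum root-mean-square deviation over the paired
#'   atoms, Angstrom.
#' @slot nAtomsUsed integer, number of atom pairs.
#' @slot pairing character vector of matched atom keys `"chain:resno:elety"`
#'   (reference frame naming).
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtomsUsed = "integer",
                 pairing = "character")
)

setValidity("SuperpositionResult", function(object) {
  if (!isTRUE(all.equal(dim(object@rotation), c(3L, 3L))))
    return("rotation must be 3x3")
  if (abs(det(object@rotation) - 1) > 1e-6)
    return("rotation must be proper (det +1)")
  if (object@rmsd < -1e-12) return("rmsd must be >= 0")
  TRUE
})
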