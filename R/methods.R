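# Accessors and show methods for the S4 containers.

#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname nFrames
#' @export
setMethod("nFrames", "DisplacementSeries", function(x) dim(x@samples)[1])

#' @rdname nFrames
#' @export
setMethod("nFrames", "WaterCount", function(x) x@nFrames)

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "DisplacementSeries", function(x) x@labels)

#' @rdname residueLabels
#' @export
setMethod("residueLabels", "OutlierReport", function(x) x@residue)

#' @rdname mutualInformationMatrix
#' @export
setMethod("mutualInformationMatrix", "CorrelationResult", function(x) x@mi)

#' @rdname generalizedCorrelationMatrix
#' @export
setMethod("generalizedCorrelationMatrix", "CorrelationResult",
          function(x) x@gcorr)

#' @rdname flaggedResidues
#' @export
setMethod("flaggedResidues", "OutlierReport",
          function(x) x@residue[x@flagged])

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (!is.na(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms\n")
})

setMethod("show", "DisplacementSeries", function(object) {
  d <- dim(object@samples)
  cat("DisplacementSeries:", d[1], "frames x", d[2], "residues",
      "(3-vector displacements, Angstrom)\n")
  if (nrow(object@trueMI) > 0)
    cat("  carries ground-truth mutual information for",
        nrow(object@trueMI), "residues\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult:", nrow(object@mi), "residues;",
      "estimator:", object@method$method %||% "?", "\n")
  off <- object@gcorr[upper.tri(object@gcorr)]
  if (length(off) > 0)
    cat(sprintf("  off-diagonal gcorr: min %.3f, median %.3f, max %.3f\n",
                min(off), stats::median(off), max(off)))
})

setMethod("show", "WaterCount", function(object) {
  cat(sprintf("WaterCount: mean %.2f waters/frame over %d frames\n",
              object@mean, object@nFrames))
})

setMethod("show", "OccupancyGrid", function(object) {
  cat("OccupancyGrid:", paste(dim(object@density), collapse = " x "),
      sprintf("voxels, spacing %.2f A, %d observations\n",
              object@spacing, object@nObservations))
})

setMethod("show", "RelaxationSeries", function(object) {
  cat("RelaxationSeries:", object@kind, "-",
      length(unique(object@records$residue)), "residues,",
      nrow(object@records), "records\n")
})

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf(
    "OutlierReport: %d residues, %d flagged (|dev - %.4f| > %.1f x %.4f)",
    length(object@residue), sum(object@flagged), object@trimmedMean,
    object@nSigma, object@sigma))
  cat(sprintf("; Spearman rho = %.3f\n", object@rho))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: RMSD %.4f A over %d atoms\n",
              object@rmsd, object@nAtomsUsed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
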