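#' Atom table accessor
#'
#' @param x a [StructureModel-class] or [Trajectory-class].
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Number of frames
#'
#' @param x a [Trajectory-class], [DisplacementSeries-class] or
#'   [WaterCount-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Residue labels
#'
#' @param x a [DisplacementSeries-class] or [OutlierReport-class].
#' @return character vector of residue identifiers.
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' Mutual information matrix accessor
#'
#' @param x a [CorrelationResult-class].
#' @return symmetric numeric matrix, nats.
#' @export
setGeneric("mutualInformationMatrix",
           function(x) standardGeneric("mutualInformationMatrix"))

#' Generalized correlation matrix accessor
#'
#' @param x a [CorrelationResult-class].
#' @return symmetric numeric matrix in `[0, 1]`.
#' @export
setGeneric("generalizedCorrelationMatrix",
           function(x) standardGeneric("generalizedCorrelationMatrix"))

#' Flagged residues of an outlier report
#'
#' @param x an [OutlierReport-class].
#' @return character vector of flagged residue identifiers.
#' @export
setGeneric("flaggedResidues", function(x) standardGeneric("flaggedResidues"))
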