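#' Accessors for crisprScreen objects
#'
#' Small accessor family used instead of direct slot access.
#'
#' @param x A crisprScreen S4 object.
#' @return \code{pamCounts}: named integer vector of per-PAM counts.
#'   \code{qcStats}: named integer vector of the read-accounting chain.
#'   \code{depletionStats}: the per-PAM statistics data.frame.
#'   \code{depletedPams}: character vector of flagged PAM words.
#'   \code{repeatRanges}/\code{spacerRanges}: \code{IRanges} of array units.
#'   \code{nRepeats}/\code{spacerLengths}: array unit counts/widths.
#'   \code{endCounts}/\code{readIntervals}: end histogram components.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pamCounts", function(x) standardGeneric("pamCounts"))
#' @rdname accessors
#' @export
setMethod("pamCounts", "PamCountTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "PamCountTable", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("qcStats", function(x) standardGeneric("qcStats"))
#' @rdname accessors
#' @export
setMethod("qcStats", "PamCountTable", function(x)
  c(total = x@nReadsTotal, passQC = x@nReadsPassQC,
    anchored = x@nReadsAnchored, distinctVariants = length(x@counts)))

#' @rdname accessors
#' @export
setGeneric("depletionStats", function(x) standardGeneric("depletionStats"))
#' @rdname accessors
#' @export
setMethod("depletionStats", "DepletionTable", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("depletedPams", function(x) standardGeneric("depletedPams"))
#' @rdname accessors
#' @export
setMethod("depletedPams", "DepletionTable", function(x)
  x@stats$pam[x@stats$depletedFlag])

#' @rdname accessors
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))
#' @rdname accessors
#' @export
setMethod("repeatRanges", "CrisprArray", function(x) x@repeats)

#' @rdname accessors
#' @export
setGeneric("spacerRanges", function(x) standardGeneric("spacerRanges"))
#' @rdname accessors
#' @export
setMethod("spacerRanges", "CrisprArray", function(x) x@spacers)

#' @rdname accessors
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))
#' @rdname accessors
#' @export
setMethod("nRepeats", "CrisprArray", function(x) length(x@repeats))

#' @rdname accessors
#' @export
setGeneric("spacerLengths", function(x) standardGeneric("spacerLengths"))
#' @rdname accessors
#' @export
setMethod("spacerLengths", "CrisprArray", function(x)
  IRanges::width(x@spacers))

#' @rdname accessors
#' @export
setGeneric("repeatConsensus", function(x) standardGeneric("repeatConsensus"))
#' @rdname accessors
#' @export
setMethod("repeatConsensus", "CrisprArray", function(x) x@repeatConsensus)

#' @rdname accessors
#' @export
setGeneric("consensusIupac", function(x) standardGeneric("consensusIupac"))
#' @rdname accessors
#' @export
setMethod("consensusIupac", "PamConsensus", function(x) x@iupac)

#' @rdname accessors
#' @export
setGeneric("endCounts", function(x) standardGeneric("endCounts"))
#' @rdname accessors
#' @export
setMethod("endCounts", "EndHistogram", function(x) x@ends)

#' @rdname accessors
#' @export
setGeneric("readIntervals", function(x) standardGeneric("readIntervals"))
#' @rdname accessors
#' @export
setMethod("readIntervals", "EndHistogram", function(x) x@reads)

#' @rdname accessors
#' @export
setGeneric("logoProbabilities", function(x) standardGeneric("logoProbabilities"))
#' @rdname accessors
#' @export
setMethod("logoProbabilities", "LogoMatrix", function(x) x@prob)

#' @rdname accessors
#' @export
setGeneric("informationContent", function(x) standardGeneric("informationContent"))
#' @rdname accessors
#' @export
setMethod("informationContent", "LogoMatrix", function(x) x@informationContent)

#' @rdname accessors
#' @export
setGeneric("positionDepletionValues", function(x) standardGeneric("positionDepletionValues"))
#' @rdname accessors
#' @export
setMethod("positionDepletionValues", "PositionProfile", function(x) x@depletionValue)

#' @rdname accessors
#' @export
setGeneric("depletedSetFrequencies", function(x) standardGeneric("depletedSetFrequencies"))
#' @rdname accessors
#' @export
setMethod("depletedSetFrequencies", "PositionProfile", function(x) x@freqDepleted)
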