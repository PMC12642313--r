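#' @include AllClasses.R
NULL

#' Accessors for AnnotationIndex, ToyGenome and related classes
#'
#' Slot access for user code goes through these rather than `@`.
#'
#' @param x an object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("annotatedJunctions", function(x) standardGeneric("annotatedJunctions"))

#' @rdname accessors
#' @export
setMethod("annotatedJunctions", "AnnotationIndex", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("annotatedDonors", function(x) standardGeneric("annotatedDonors"))

#' @rdname accessors
#' @export
setMethod("annotatedDonors", "AnnotationIndex", function(x) x@donors)

#' @rdname accessors
#' @export
setGeneric("annotatedAcceptors", function(x) standardGeneric("annotatedAcceptors"))

#' @rdname accessors
#' @export
setMethod("annotatedAcceptors", "AnnotationIndex", function(x) x@acceptors)

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setMethod("geneRanges", "AnnotationIndex", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @export
setMethod("genomeSeq", "ToyGenome", function(x) x@genome)

#' @rdname accessors
#' @export
setGeneric("plantedCE", function(x) standardGeneric("plantedCE"))

#' @rdname accessors
#' @export
setMethod("plantedCE", "ToyGenome", function(x) x@ce)

#' @rdname accessors
#' @export
setGeneric("crypticPeptide", function(x) standardGeneric("crypticPeptide"))

#' @rdname accessors
#' @export
setMethod("crypticPeptide", "ToyGenome", function(x) x@peptide)

#' @rdname accessors
#' @export
setGeneric("referenceModel", function(x) standardGeneric("referenceModel"))

#' @rdname accessors
#' @export
setMethod("referenceModel", "ToyGenome", function(x) x@model)

#' @rdname accessors
#' @export
setGeneric("referenceProtein", function(x) standardGeneric("referenceProtein"))

#' @rdname accessors
#' @export
setMethod("referenceProtein", "ToyGenome", function(x) x@referenceProtein)

#' @rdname accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname accessors
#' @export
setMethod("geneAnnotation", "ToyGenome", function(x) x@annotation)

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname accessors
#' @export
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("cdsBounds", function(x) standardGeneric("cdsBounds"))

#' @rdname accessors
#' @export
setMethod("cdsBounds", "TranscriptModel",
          function(x) c(start = x@cdsStart, end = x@cdsEnd))

#' @rdname accessors
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))

#' @rdname accessors
#' @export
setMethod("proteinSequence", "ProteinProduct", function(x) x@protein)

#' @rdname accessors
#' @export
setGeneric("crypticSuffix", function(x) standardGeneric("crypticSuffix"))

#' @rdname accessors
#' @export
setMethod("crypticSuffix", "ProteinProduct", function(x) x@crypticSuffix)

#' @rdname accessors
#' @export
setGeneric("isTruncated", function(x) standardGeneric("isTruncated"))

#' @rdname accessors
#' @export
setMethod("isTruncated", "ProteinProduct", function(x) x@truncated)

#' @rdname accessors
#' @export
setGeneric("stopInCE", function(x) standardGeneric("stopInCE"))

#' @rdname accessors
#' @export
setMethod("stopInCE", "ProteinProduct", function(x) x@stopInCE)

#' @rdname accessors
#' @export
setGeneric("isNmdCandidate", function(x) standardGeneric("isNmdCandidate"))

#' @rdname accessors
#' @export
setMethod("isNmdCandidate", "ProteinProduct", function(x) x@nmdCandidate)
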