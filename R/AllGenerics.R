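#' @include AllClasses.R
NULL

#' @rdname Genome-class
#' @param object,x An object of the documented class.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname Genome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname Genome-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname Genome-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname BipartiteMotif-class
#' @export
setGeneric("motifSpan", function(x) standardGeneric("motifSpan"))

#' @rdname BipartiteMotif-class
#' @export
setGeneric("specifiedBases", function(x) standardGeneric("specifiedBases"))

#' @rdname BipartiteMotif-class
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))

#' @rdname BipartiteMotif-class
#' @export
setGeneric("motifLabel", function(x) standardGeneric("motifLabel"))

#' @rdname BipartiteMotif-class
#' @export
setGeneric("motifString", function(x) standardGeneric("motifString"))

#' @rdname BipartiteMotif-class
#' @export
setGeneric("isPalindromic", function(x) standardGeneric("isPalindromic"))

#' @rdname TSSCollection-class
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))

#' @rdname TSSCollection-class
#' @export
setGeneric("tssStrands", function(x) standardGeneric("tssStrands"))

#' @rdname TSSCollection-class
#' @export
setGeneric("tssSource", function(x) standardGeneric("tssSource"))

#' Rigid circular shift of a TSS collection
#'
#' Adds a single offset `delta` to every TSS position modulo the genome
#' length `L`, preserving the relative spacing (and strands) of the set.
#' This is the elementary move of the rotation permutation null: under the
#' null hypothesis that promoter windows carry no information about site
#' placement, every rotation of the TSS set is equally likely.
#'
#' @param x A [TSSCollection-class].
#' @param delta Integer shift in `[1, L]`; `delta = L` is the identity.
#' @param L Genome length in bases (the modulus).
#' @return A shifted [TSSCollection-class].
#' @examples
#' tss <- newTssCollection("g", c(10L, 20L), c("+", "-"))
#' tssPositions(circularShift(tss, 5L, 100L))
#' @export
setGeneric("circularShift", function(x, delta, L)
  standardGeneric("circularShift"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("observedHits", function(x) standardGeneric("observedHits"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("pDepletion", function(x) standardGeneric("pDepletion"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("pEnrichment", function(x) standardGeneric("pEnrichment"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("pAdjusted", function(x) standardGeneric("pAdjusted"))
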