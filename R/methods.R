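#' @include AllGenerics.R
NULL

# ---- Genome -----------------------------------------------------------------

#' Construct a Genome from a character sequence
#'
#' Normalizes the sequence to uppercase and validates the alphabet
#' (\{A,C,G,T,N\}; U and protein characters are rejected).
#'
#' @param id Record identifier.
#' @param sequence Character scalar or [Biostrings::DNAString].
#' @param circular Logical; defaults to `TRUE` (bacterial replicon).
#' @return A [Genome-class].
#' @examples
#' g <- newGenome("g", "acGT")
#' genomeLength(g)
#' @export
newGenome <- function(id, sequence, circular = TRUE) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence for '", id, "' contains characters outside {A,C,G,T,N}")
  new("Genome", id = as.character(id), sequence = DNAString(sequence),
      circular = isTRUE(circular))
}

#' @rdname Genome-class
#' @export
setMethod("genomeId", "Genome", function(x) x@id)

#' @rdname Genome-class
#' @export
setMethod("genomeSeq", "Genome", function(x) x@sequence)

#' @rdname Genome-class
#' @export
setMethod("genomeLength", "Genome", function(x) length(x@sequence))

#' @rdname Genome-class
#' @export
setMethod("isCircular", "Genome", function(x) x@circular)

setMethod("show", "Genome", function(object) {
  cat("Genome '", object@id, "': ", length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", "\n", sep = "")
})

# ---- BipartiteMotif ---------------------------------------------------------

#' @rdname BipartiteMotif-class
#' @export
setMethod("motifSpan", "BipartiteMotif", function(x)
  nchar(x@half1) + x@spacer + nchar(x@half2))

#' @rdname BipartiteMotif-class
#' @export
setMethod("specifiedBases", "BipartiteMotif", function(x) {
  chars <- strsplit(paste0(x@half1, x@half2), "")[[1]]
  sum(chars != "N")
})

#' @rdname BipartiteMotif-class
#' @export
setMethod("spacerLength", "BipartiteMotif", function(x) x@spacer)

#' @rdname BipartiteMotif-class
#' @export
setMethod("motifLabel", "BipartiteMotif", function(x) x@label)

#' @rdname BipartiteMotif-class
#' @export
setMethod("motifString", "BipartiteMotif", function(x)
  paste0(x@half1, strrep("N", x@spacer), x@half2))

#' @rdname BipartiteMotif-class
#' @export
setMethod("isPalindromic", "BipartiteMotif", function(x) {
  s <- motifString(x)
  s == as.character(Biostrings::reverseComplement(DNAString(s)))
})

#' Reverse complement of a bipartite motif
#'
#' IUPAC-aware complement (W maps to W, N to N) with the half-sites swapped
#' and individually reversed; the spacer length is preserved. The label is
#' kept, since both orientations describe the same physical duplex site.
#'
#' @param x A [BipartiteMotif-class].
#' @return A [BipartiteMotif-class].
#' @examples
#' rc <- reverseComplement(parseMotif("CCA(N7)CTTC"))
#' motifString(rc)  # GAAGNNNNNNNTGG
#' @aliases reverseComplement
#' @export
setMethod("reverseComplement", "BipartiteMotif", function(x, ...) {
  rc <- function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(DNAString(s)))
  }
  if (nzchar(x@half2)) {
    new("BipartiteMotif", half1 = rc(x@half2), spacer = x@spacer,
        half2 = rc(x@half1), label = x@label)
  } else {
    new("BipartiteMotif", half1 = rc(x@half1), spacer = x@spacer,
        half2 = "", label = x@label)
  }
})

setMethod("show", "BipartiteMotif", function(object) {
  cat("BipartiteMotif '", object@label, "': ", object@half1,
      if (object@spacer > 0L) paste0("(N", object@spacer, ")") else "",
      object@half2, " (span ", motifSpan(object), ", ",
      specifiedBases(object), " specified bases",
      if (isPalindromic(object)) ", palindromic" else "", ")\n", sep = "")
})

# ---- TSSCollection ----------------------------------------------------------

#' Construct a TSSCollection from vectors
#'
#' @param genomeId Genome identifier the sites live on.
#' @param positions Integer vector of 0-based positions.
#' @param strands Character vector of "+"/"-".
#' @param source Label for the TSS set.
#' @return A [TSSCollection-class].
#' @export
newTssCollection <- function(genomeId, positions, strands,
                             source = "tss") {
  new("TSSCollection", genomeId = as.character(genomeId),
      positions = as.integer(positions), strands = as.character(strands),
      source = as.character(source))
}

#' @rdname TSSCollection-class
#' @export
setMethod("tssPositions", "TSSCollection", function(x) x@positions)

#' @rdname TSSCollection-class
#' @export
setMethod("tssStrands", "TSSCollection", function(x) x@strands)

#' @rdname TSSCollection-class
#' @export
setMethod("tssSource", "TSSCollection", function(x) x@source)

#' @rdname TSSCollection-class
#' @export
setMethod("length", "TSSCollection", function(x) length(x@positions))

#' @rdname circularShift
#' @export
setMethod("circularShift", "TSSCollection", function(x, delta, L) {
  delta <- as.integer(delta); L <- as.integer(L)
  if (length(delta) != 1L || is.na(delta) || delta < 1L || delta > L)
    stop("'delta' must lie in [1, L]")
  if (length(x@positions) && any(x@positions >= L))
    stop("TSS positions must lie in [0, L)")
  new("TSSCollection", genomeId = x@genomeId,
      positions = (x@positions + delta) %% L,
      strands = x@strands, source = x@source)
})

setMethod("show", "TSSCollection", function(object) {
  cat("TSSCollection '", object@source, "' on '", object@genomeId, "': ",
      length(object@positions), " sites\n", sep = "")
})

# ---- EnrichmentResult -------------------------------------------------------

#' @rdname EnrichmentResult-class
#' @export
setMethod("observedHits", "EnrichmentResult", function(x) x@observed)

#' @rdname EnrichmentResult-class
#' @export
setMethod("nullCounts", "EnrichmentResult", function(x) x@nullCounts)

#' @rdname EnrichmentResult-class
#' @export
setMethod("pDepletion", "EnrichmentResult", function(x) x@pDepletion)

#' @rdname EnrichmentResult-class
#' @export
setMethod("pEnrichment", "EnrichmentResult", function(x) x@pEnrichment)

#' @rdname EnrichmentResult-class
#' @export
setMethod("pAdjusted", "EnrichmentResult", function(x) x@pAdjusted)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult: motif '", object@motifLabel, "' vs TSS set '",
      object@tssSource, "'\n", sep = "")
  cat("  statistic: ", object@statistic, "; observed = ", object@observed,
      "; null mean = ", round(mean(object@nullCounts), 2),
      " (B = ", object@B,
      if (object@exhaustive) ", exhaustive" else "", ")\n", sep = "")
  cat("  p(depletion) = ", signif(object@pDepletion, 4),
      ", p(enrichment) = ", signif(object@pEnrichment, 4),
      ", adjusted (m = ", object@mTests, ") = ",
      signif(object@pAdjusted, 4), "\n", sep = "")
})
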