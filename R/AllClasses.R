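#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement IUPAC_CODE_MAP
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom stats runif setNames pnorm ks.test
#' @importFrom utils read.delim write.table head
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Genome: a single DNA sequence with topology
#'
#' Container for one genome record: an identifier, an uppercase DNA
#' sequence over \{A, C, G, T, N\} and a circularity flag. Bacterial
#' chromosomes and most plasmids are circular; the circular flag controls
#' whether motif scans and promoter windows are allowed to wrap across the
#' sequence origin.
#'
#' All coordinates used by the package are 0-based half-open; conversion to
#' the 1-based conventions of GFF3 and TSV tables happens only when files
#' are read or written.
#'
#' @slot id Character scalar, the record identifier (FASTA header token).
#' @slot sequence A [Biostrings::DNAString] holding the uppercase sequence.
#' @slot circular Logical scalar; `TRUE` for a circular replicon.
#'
#' @seealso [readFasta()], [scanGenome()]
#' @exportClass Genome
setClass("Genome",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  letters <- Biostrings::uniqueLetters(object@sequence)
  bad <- setdiff(letters, VALID_BASES)
  if (length(bad))
    msg <- c(msg, paste0("sequence contains non-{A,C,G,T,N} characters: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' BipartiteMotif: a degenerate recognition sequence
#'
#' Recognition motif of a DNA methyltransferase or restriction enzyme,
#' modelled as two specified IUPAC half-sites separated by a fixed-length
#' unspecified spacer, the classical bipartite target of Type I
#' restriction-modification systems (e.g. `CCA(N7)CTTC`). Plain contiguous
#' motifs such as `GATC` or `CCWGG` are the degenerate special case with a
#' zero-length spacer and an empty second half-site.
#'
#' @slot half1 IUPAC string, the 5' specified half-site.
#' @slot spacer Integer >= 0, number of unspecified (N) spacer positions.
#' @slot half2 IUPAC string, the 3' specified half-site (may be empty).
#' @slot label Character scalar used to tag sites and result rows.
#'
#' @seealso [parseMotif()], [scanGenome()], [motifSpan()]
#' @exportClass BipartiteMotif
setClass("BipartiteMotif",
  representation(half1 = "character", spacer = "integer",
                 half2 = "character", label = "character"))

setValidity("BipartiteMotif", function(object) {
  msg <- character()
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  chk <- function(x, what) {
    if (length(x) != 1L || is.na(x))
      return(paste0("'", what, "' must be a single string"))
    if (nzchar(x) && !all(strsplit(x, "")[[1]] %in% iupac))
      return(paste0("'", what, "' contains non-IUPAC characters"))
    NULL
  }
  msg <- c(msg, chk(object@half1, "half1"), chk(object@half2, "half2"))
  if (!nzchar(object@half1))
    msg <- c(msg, "'half1' must be non-empty")
  if (length(object@spacer) != 1L || is.na(object@spacer) ||
      object@spacer < 0L)
    msg <- c(msg, "'spacer' must be a single non-negative integer")
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' TSSCollection: a set of transcription start sites
#'
#' A named collection of transcription start sites on one genome, with
#' per-site strands. Positions are stored 0-based; TSV input/output uses
#' 1-based positions. The collection supports rigid circular shifts, the
#' elementary move of the rotation permutation null.
#'
#' @slot genomeId Character scalar naming the genome the sites live on.
#' @slot positions Integer vector of 0-based TSS positions.
#' @slot strands Character vector of "+"/"-", parallel to `positions`.
#' @slot source Character scalar labelling the TSS set (e.g. the study it
#'   was mapped in).
#'
#' @seealso [readTssTable()], [circularShift()], [runPermutation()]
#' @exportClass TSSCollection
setClass("TSSCollection",
  representation(genomeId = "character", positions = "integer",
                 strands = "character", source = "character"))

setValidity("TSSCollection", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@strands))
    msg <- c(msg, "'positions' and 'strands' must have equal length")
  if (length(object@positions) && any(object@positions < 0L))
    msg <- c(msg, "all positions must be >= 0")
  if (length(object@strands) && !all(object@strands %in% c("+", "-")))
    msg <- c(msg, "strands must be '+' or '-'")
  if (length(object@genomeId) != 1L || length(object@source) != 1L)
    msg <- c(msg, "'genomeId' and 'source' must be single strings")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: outcome of the circular-shift permutation test
#'
#' Holds the observed promoter-overlap statistic for one motif against one
#' TSS set, the null distribution obtained by rigid circular shifts of the
#' TSS positions, both one-sided empirical P-values, and the
#' Bonferroni-adjusted headline (depletion-direction) P-value.
#'
#' Empirical P-values use the add-one convention \eqn{(k+1)/(B+1)} so they
#' are never zero; the raw tie-inclusive counts `kLe` (replicates with null
#' statistic <= observed) and `kGe` (null >= observed) are retained so the
#' plain replicate-counting convention is recoverable. When the test is run
#' in exhaustive mode (all L shifts enumerated) the P-values are the exact
#' enumeration fractions `kLe/B` and `kGe/B`.
#'
#' @slot motifLabel,tssSource Labels identifying the tested pair.
#' @slot observed Integer, the observed overlap statistic.
#' @slot nullCounts Integer vector of per-replicate null statistics.
#' @slot B Integer, number of null replicates.
#' @slot kLe,kGe Integers, tie-inclusive tail counts.
#' @slot pDepletion,pEnrichment One-sided empirical P-values.
#' @slot pAdjusted Bonferroni-adjusted depletion P-value, `min(1, m * p)`.
#' @slot mTests Integer, Bonferroni multiplier.
#' @slot seed Integer seed that generated the replicate stream.
#' @slot statistic Either "windows" (windows with >= 1 site) or "pairs".
#' @slot exhaustive Logical, whether all shifts were enumerated.
#'
#' @seealso [runPermutation()], [bonferroniAdjust()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(motifLabel = "character", tssSource = "character",
                 observed = "integer", nullCounts = "integer",
                 B = "integer", kLe = "integer", kGe = "integer",
                 pDepletion = "numeric", pEnrichment = "numeric",
                 pAdjusted = "numeric", mTests = "integer",
                 seed = "integer", statistic = "character",
                 exhaustive = "logical"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (length(object@nullCounts) != object@B)
    msg <- c(msg, "'nullCounts' must have length B")
  if (object@kLe + object@kGe < object@B)
    msg <- c(msg, "tie accounting violated: kLe + kGe < B")
  p <- c(object@pDepletion, object@pEnrichment, object@pAdjusted)
  if (any(p <= 0) || any(p > 1))
    msg <- c(msg, "P-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: parameters for generating test data with known truth
#'
#' Describes a synthetic dataset: a random circular (or linear) genome of
#' given length and GC content, a set of motif sites planted at known
#' positions, a non-overlapping ORF annotation, and a TSS collection drawn
#' either independently of the sites (the exact rotation null) or with a
#' tunable avoidance of site-overlapping promoter windows (a planted
#' depletion signal).
#'
#' The defaults mirror the scale at which the permutation test is
#' exercised in calibration and power studies: a 100 kb circular genome at
#' 50% GC carrying 300 sites of the 14 bp bipartite motif `CCA(N7)CTTC`,
#' 500 TSSs, and 50 bp promoter windows.
#'
#' @slot L Genome length in bases.
#' @slot gc GC proportion in (0, 1).
#' @slot circular Logical topology flag.
#' @slot motif A [BipartiteMotif-class] to plant and scan for.
#' @slot nSites Number of sites to plant.
#' @slot nOrfs Number of non-overlapping ORFs to place.
#' @slot orfLengthRange Integer length-2 vector, ORF length bounds in bases.
#' @slot nTss Number of transcription start sites to draw.
#' @slot width Promoter window width in bases.
#' @slot avoidProb Probability in [0, 1] that a TSS draw whose upstream
#'   window overlaps a site is rejected and redrawn; 0 gives the exact
#'   null, values near 1 plant strong depletion.
#' @slot seed Integer seed governing all generators.
#'
#' @seealso [syntheticScenario()], [genGenome()], [genTss()]
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(L = "integer", gc = "numeric", circular = "logical",
                 motif = "BipartiteMotif", nSites = "integer",
                 nOrfs = "integer", orfLengthRange = "integer",
                 nTss = "integer", width = "integer",
                 avoidProb = "numeric", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@L < 1L) msg <- c(msg, "'L' must be positive")
  if (object@gc <= 0 || object@gc >= 1)
    msg <- c(msg, "'gc' must lie strictly between 0 and 1")
  if (object@avoidProb < 0 || object@avoidProb > 1)
    msg <- c(msg, "'avoidProb' must lie in [0, 1]")
  if (length(object@orfLengthRange) != 2L ||
      object@orfLengthRange[1L] > object@orfLengthRange[2L])
    msg <- c(msg, "'orfLengthRange' must be an increasing length-2 vector")
  if (any(c(object@nSites, object@nOrfs, object@nTss) < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})
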