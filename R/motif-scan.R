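#' @include methods.R
NULL

#' Parse a motif written in bipartite notation
#'
#' Accepts the field's standard notation for Type I recognition sequences,
#' `HALF1(Nk)HALF2` — e.g. `CCA(N7)CTTC`, optionally decorated as
#' `5'-CCA(N_7_)CTTC-3'` — as well as plain IUPAC words (`GATC`, `CCWGG`),
#' which parse to a zero-length spacer and an empty second half-site.
#'
#' @param text Motif in bipartite or plain IUPAC notation.
#' @param label Optional label; defaults to the canonical undecorated form.
#' @return A [BipartiteMotif-class].
#' @examples
#' m <- parseMotif("5'-CCA(N7)CTTC-3'")
#' motifSpan(m)       # 14
#' specifiedBases(m)  # 7
#' @export
parseMotif <- function(text, label = NULL) {
  s <- toupper(text)
  # strip 5'/3' decorations (straight or typographic primes), underscores,
  # hyphens and whitespace
  s <- gsub("5['′]|3['′]", "", s)
  s <- gsub("[-_[:space:]]", "", s)
  m <- regmatches(s, regexec("^([A-Z]+)\\(N([0-9]+)\\)([A-Z]+)$", s))[[1]]
  if (length(m) == 4L) {
    half1 <- m[2L]; spacer <- as.integer(m[3L]); half2 <- m[4L]
  } else if (grepl("^[A-Z]+$", s)) {
    half1 <- s; spacer <- 0L; half2 <- ""
  } else {
    stop("cannot parse motif '", text,
         "': expected HALF1(Nk)HALF2 or a plain IUPAC word")
  }
  canonical <- if (nzchar(half2))
    paste0(half1, "(N", spacer, ")", half2) else half1
  new("BipartiteMotif", half1 = half1, spacer = spacer, half2 = half2,
      label = label %||% canonical)
}

# Bit codes: A=1, C=2, G=4, T=8. A genome N gets 0 bits, so it can never
# satisfy a specified pattern position; spacer positions are skipped
# entirely, so N matches there. Pattern IUPAC codes become the union of
# their base bits.
.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.seqBits <- function(seqchar) {
  chars <- strsplit(seqchar, "")[[1]]
  bits <- .BASE_BITS[chars]
  bits[is.na(bits)] <- 0L  # N (and only N, after Genome validation)
  unname(bits)
}

# per-position pattern bits; NA marks wildcard (spacer / literal N)
.patternBits <- function(motif) {
  chars <- strsplit(motifString(motif), "")[[1]]
  vapply(chars, function(ch) {
    if (ch == "N") return(NA_integer_)
    sum(.BASE_BITS[strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]])
  }, integer(1), USE.NAMES = FALSE)
}

# starts (0-based) of pattern matches in a bit vector
.matchStarts <- function(bits, pat) {
  n <- length(bits) - length(pat) + 1L
  if (n < 1L) return(integer(0))
  ok <- rep(TRUE, n)
  idx <- seq_len(n)
  for (o in seq_along(pat)) {
    p <- pat[o]
    if (is.na(p)) next
    ok <- ok & (bitwAnd(bits[idx + (o - 1L)], p) > 0L)
  }
  which(ok) - 1L
}

#' Scan a genome for all duplex occurrences of a motif
#'
#' Finds every occurrence of the motif or its reverse complement on the
#' forward strand, reporting each physical duplex site exactly once:
#' matches of the written motif get orientation "+", matches of its reverse
#' complement orientation "-", and palindromic motifs (equal to their own
#' reverse complement as degenerate patterns, e.g. GATC, CCWGG) are matched
#' once with orientation "+". On circular genomes occurrences wrapping the
#' origin are included, with `start` the position of the leftmost base in
#' `[0, L)` and `start + span` possibly exceeding `L`. Overlapping
#' occurrences are all reported. Genome N bases never match a specified
#' motif position but do match spacer positions.
#'
#' @param genome A [Genome-class].
#' @param motif A [BipartiteMotif-class].
#' @param circular Override the genome's topology flag.
#' @return A data frame with columns `genome_id`, `start` (0-based),
#'   `span`, `orientation` ("+"/"-"), `motif_label`, sorted by `start`
#'   with "+" before "-" on ties.
#' @examples
#' g <- newGenome("g", "CCAAAAAAAACTTC", circular = FALSE)
#' scanGenome(g, parseMotif("CCA(N7)CTTC"))
#' @export
scanGenome <- function(genome, motif, circular = isCircular(genome)) {
  L <- genomeLength(genome)
  span <- motifSpan(motif)
  if (span > L)
    stop("motif span (", span, ") exceeds genome length (", L, ")")
  seqchar <- as.character(genomeSeq(genome))
  bits <- .seqBits(seqchar)
  if (circular && span > 1L)
    bits <- c(bits, bits[seq_len(span - 1L)])
  pal <- isPalindromic(motif)
  fwd <- .matchStarts(bits, .patternBits(motif))
  starts <- fwd
  orient <- rep("+", length(fwd))
  if (!pal) {
    rev <- .matchStarts(bits, .patternBits(reverseComplement(motif)))
    starts <- c(starts, rev)
    orient <- c(orient, rep("-", length(rev)))
  }
  keep <- starts < L
  starts <- starts[keep]; orient <- orient[keep]
  # a degenerate motif can match both orientations at one position; that is
  # a single physical duplex site — keep "+"
  ord <- order(starts, orient)
  starts <- starts[ord]; orient <- orient[ord]
  dup <- duplicated(starts)
  starts <- starts[!dup]; orient <- orient[!dup]
  data.frame(genome_id = rep(genomeId(genome), length(starts)),
             start = as.integer(starts), span = rep(span, length(starts)),
             orientation = orient,
             motif_label = rep(motifLabel(motif), length(starts)),
             stringsAsFactors = FALSE)
}

#' Count motif sites across one or more genome records
#'
#' Runs [scanGenome()] for each motif on each record of an assembly
#' (chromosome plus any plasmids) and tabulates duplex site counts,
#' summed across records or restricted to the largest record
#' (chromosome-only mode).
#'
#' @param genomes A [Genome-class] or list of them (one per FASTA record).
#' @param motifs A [BipartiteMotif-class] or list of them.
#' @param restrictToLargest If `TRUE`, count only on the longest record.
#' @return A data frame with columns `motif_label` and `count`, plus a
#'   `"perRecord"` attribute holding the motif x record count matrix.
#' @export
countSites <- function(genomes, motifs, restrictToLargest = FALSE) {
  if (is(genomes, "Genome")) genomes <- list(genomes)
  if (is(motifs, "BipartiteMotif")) motifs <- list(motifs)
  if (restrictToLargest) {
    lens <- vapply(genomes, genomeLength, integer(1))
    genomes <- genomes[which.max(lens)]
  }
  per <- vapply(genomes, function(g)
    vapply(motifs, function(m) nrow(scanGenome(g, m)), integer(1)),
    integer(length(motifs)))
  per <- matrix(per, nrow = length(motifs),
                dimnames = list(vapply(motifs, motifLabel, character(1)),
                                vapply(genomes, genomeId, character(1))))
  out <- data.frame(motif_label = rownames(per),
                    count = as.integer(rowSums(per)),
                    stringsAsFactors = FALSE)
  attr(out, "perRecord") <- per
  out
}
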