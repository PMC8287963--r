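#' @include site-context.R
NULL

# Fast rotation counter.
#
# Shifting every TSS by delta shifts every window start rigidly by delta,
# so the overlap statistic at shift delta only needs the (fixed, sorted)
# site starts. Under "span" mode a window starting at `lo` overlaps a site
# of span `sp` iff the site's start lies in the circular interval
# [lo - sp + 1, lo + width), of length width + sp - 1; under "start" mode
# the interval is [lo, lo + width). Counting site starts in a circular
# interval is two findInterval() lookups on the sorted starts, so one
# replicate costs O(n_windows * log n_sites) per distinct span.
.rotationCounter <- function(tssPos, tssStrand, sites, L, width,
                             mode = "span", statistic = "windows") {
  lo0 <- .windowLo(as.integer(tssPos), tssStrand, as.integer(width))
  nw <- length(lo0)
  bySpan <- split(sites$start, if (mode == "span") sites$span
                  else rep(1L, nrow(sites)))
  groups <- lapply(names(bySpan), function(k) {
    sp <- if (mode == "span") as.integer(k) else 1L
    list(S = sort(as.integer(bySpan[[k]])),
         ext = if (mode == "span") sp - 1L else 0L)
  })
  width <- as.integer(width)
  function(delta) {
    if (nw == 0L) return(0L)
    total <- if (statistic == "windows") logical(nw) else 0L
    for (g in groups) {
      n <- length(g$S)
      len <- width + g$ext
      if (len >= L) {
        cnt <- rep(n, nw)
      } else {
        a <- (lo0 + delta - g$ext) %% L
        b <- a + len
        cLTa <- findInterval(a - 0.5, g$S)
        cLTb <- findInterval(pmin(b, L) - 0.5, g$S)
        cnt <- cLTb - cLTa
        wrap <- b > L
        if (any(wrap))
          cnt[wrap] <- (n - cLTa[wrap]) +
            findInterval(b[wrap] - L - 0.5, g$S)
      }
      if (statistic == "windows") total <- total | (cnt > 0L)
      else total <- total + sum(cnt)
    }
    if (statistic == "windows") sum(total) else as.integer(total)
  }
}

#' Circular-shift permutation test for promoter overlap
#'
#' Tests whether methylation sites are depleted (or enriched) in the
#' promoter windows upstream of a TSS set, against a rotation null: for
#' each of `B` replicates one random offset delta, uniform on
#' \{1, ..., L\}, is added to all TSS positions modulo the genome length,
#' the 50 bp (by default) upstream windows are rebuilt at the shifted
#' positions, and the overlap statistic is recounted. The rigid shift
#' preserves the spatial structure of the TSS set, so the null retains
#' every feature of both point patterns except their relative phase.
#'
#' The depletion P-value counts replicates with an equal or smaller
#' statistic than observed; the enrichment P-value counts equal or larger.
#' Both use the add-one convention \eqn{(k+1)/(B+1)}, with the raw tail
#' counts kept in the result. With `exhaustive = TRUE` all `L` shifts are
#' enumerated instead of sampled and the P-values are the exact fractions
#' `k/L` (the identity shift is part of the rotation group, so they are
#' never zero). The adjusted value is the Bonferroni-corrected headline
#' depletion P, `min(1, mTests * pDepletion)`.
#'
#' @param sites Site data frame from [scanGenome()].
#' @param tss A [TSSCollection-class].
#' @param L Genome length in bases; the genome is treated as circular.
#' @param width Promoter window width in bases (default 50).
#' @param B Number of replicates (default 10000).
#' @param seed Integer seed for the replicate stream; identical seed and
#'   inputs reproduce the null counts exactly.
#' @param mode Overlap mode, "span" (default) or "start".
#' @param statistic "windows" (number of windows with >= 1 site, default)
#'   or "pairs" (number of overlapping window-site pairs).
#' @param exhaustive Enumerate all `L` shifts instead of sampling.
#' @param mTests Bonferroni multiplier (default 1; pipelines set it to the
#'   number of motif x TSS-set combinations).
#' @param maxCost Guard on `B * length(tss)`; raise for very large runs.
#' @param label Motif label for the result; defaults to the label carried
#'   by `sites` (or "none" when there are no sites).
#' @return An [EnrichmentResult-class].
#' @examples
#' sites <- data.frame(genome_id = "g", start = 10L, span = 4L,
#'                     orientation = "+", motif_label = "GATC")
#' tss <- newTssCollection("g", 40L, "+")
#' runPermutation(sites, tss, L = 100L, width = 10L, B = 200L, seed = 1L)
#' @export
runPermutation <- function(sites, tss, L, width = 50L, B = 10000L,
                           seed = 1L, mode = c("span", "start"),
                           statistic = c("windows", "pairs"),
                           exhaustive = FALSE, mTests = 1L,
                           maxCost = 2e9, label = NULL) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  L <- as.integer(L); width <- as.integer(width)
  B <- if (exhaustive) L else as.integer(B)
  if (B < 1L) stop("'B' must be >= 1")
  if (width >= L) stop("'width' must be smaller than the genome length")
  if (nrow(sites) && !all(sites$genome_id == tss@genomeId))
    stop("sites and TSS collection refer to different genomes ('",
         sites$genome_id[1L], "' vs '", tss@genomeId, "')")
  if (length(tss) == 0L)
    warning("empty TSS collection: observed statistic is 0 by construction")
  if (as.double(B) * max(1L, length(tss)) > maxCost)
    stop("B * number of TSSs exceeds maxCost (", maxCost,
         "); raise 'maxCost' to run anyway")
  counter <- .rotationCounter(tssPositions(tss), tssStrands(tss), sites,
                              L, width, mode, statistic)
  observed <- counter(L)  # delta = L is the identity rotation
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(seed)
  deltas <- if (exhaustive) seq_len(L) else
    sample.int(L, B, replace = TRUE)
  nullCounts <- vapply(deltas, counter, integer(1))
  kLe <- sum(nullCounts <= observed)
  kGe <- sum(nullCounts >= observed)
  if (exhaustive) {
    pDep <- kLe / B; pEnr <- kGe / B
  } else {
    pDep <- (kLe + 1) / (B + 1); pEnr <- (kGe + 1) / (B + 1)
  }
  if (is.null(label))
    label <- if (nrow(sites)) sites$motif_label[1L] else "none"
  new("EnrichmentResult",
      motifLabel = label,
      tssSource = tssSource(tss), observed = as.integer(observed),
      nullCounts = nullCounts, B = B, kLe = as.integer(kLe),
      kGe = as.integer(kGe), pDepletion = pDep, pEnrichment = pEnr,
      pAdjusted = min(1, as.integer(mTests) * pDep),
      mTests = as.integer(mTests), seed = as.integer(seed),
      statistic = statistic, exhaustive = exhaustive)
}

#' Bonferroni correction for a family of empirical P-values
#'
#' Maps each P-value to `min(1, m * p)`, the correction applied before
#' declaring significance at P < 0.05 across the motif x TSS-set family.
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @param m Family size, at least `length(p)`.
#' @return Adjusted P-values, same length as `p`.
#' @examples
#' bonferroniAdjust(c(0.01, 0.5), m = 5)
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p <= 0) || any(p > 1)) stop("P-values must lie in (0, 1]")
  if (m < length(p)) stop("'m' must be at least length(p)")
  pmin(1, m * p)
}
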