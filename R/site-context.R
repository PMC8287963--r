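#' @include motif-scan.R
NULL

# conceptual (unwrapped) 0-based start of the upstream window
.windowLo <- function(pos, strand, width) {
  ifelse(strand == "+", pos - width, pos + 1L)
}

# Segments for one window start `lo` of length `width`. Circular windows
# wrap (never truncate); linear windows are clipped at [0, L).
.windowSegments <- function(lo, width, L, circular) {
  if (circular) {
    a <- ((lo %% L) + L) %% L
    b <- a + width
    if (b <= L)
      list(segs = cbind(start = a, end = b), truncated = FALSE)
    else
      list(segs = cbind(start = c(a, 0L), end = c(L, b - L)),
           truncated = FALSE)
  } else {
    a <- max(lo, 0L); b <- min(lo + width, L)
    if (b <= a)
      list(segs = cbind(start = integer(0), end = integer(0)),
           truncated = TRUE)
    else
      list(segs = cbind(start = a, end = b),
           truncated = (a > lo) || (b < lo + width))
  }
}

#' Build the promoter window upstream of one TSS
#'
#' The putative promoter is the `width`-bp window immediately upstream of
#' the TSS, with upstream defined relative to the direction of
#' transcription and the TSS base itself excluded: for a "+" TSS at
#' 0-based position p the window covers `[p - width, p)`; for a "-" TSS it
#' covers `[p + 1, p + 1 + width)`. On a circular genome the window wraps
#' across the origin (two segments); on a linear genome it is truncated at
#' the boundary and flagged.
#'
#' @param tssPosition 0-based TSS position in `[0, L)`.
#' @param strand "+" or "-".
#' @param width Window width in bases (default 50).
#' @param L Genome length.
#' @param circular Logical topology flag.
#' @return A list with elements `segments` (matrix of 0-based half-open
#'   `start`/`end` rows), `tss_position`, `strand`, `width`, `covered`
#'   (total bases) and `truncated`.
#' @examples
#' promoterWindow(999L, "+", 50L, 1e6L, circular = FALSE)$segments
#' promoterWindow(9L, "+", 50L, 100L, circular = TRUE)$segments
#' @export
promoterWindow <- function(tssPosition, strand, width = 50L, L,
                           circular = TRUE) {
  width <- as.integer(width); L <- as.integer(L)
  tssPosition <- as.integer(tssPosition)
  if (width < 1L) stop("'width' must be >= 1")
  if (width >= L) stop("'width' must be smaller than the genome length")
  if (tssPosition < 0L || tssPosition >= L)
    stop("'tssPosition' must lie in [0, L)")
  if (!strand %in% c("+", "-")) stop("'strand' must be '+' or '-'")
  w <- .windowSegments(.windowLo(tssPosition, strand, width), width, L,
                       circular)
  list(segments = w$segs, tss_position = tssPosition, strand = strand,
       width = width, covered = sum(w$segs[, "end"] - w$segs[, "start"]),
       truncated = w$truncated)
}

#' Build promoter windows for a whole TSS collection
#'
#' Vectorized companion of [promoterWindow()]: one row per window segment,
#' windows indexed by `window_id` in TSS order.
#'
#' @param tss A [TSSCollection-class], or an integer vector of 0-based
#'   positions (then `strands` must be given).
#' @param strands Strand vector when `tss` is a plain position vector.
#' @inheritParams promoterWindow
#' @return A data frame of segments with columns `window_id`,
#'   `tss_position`, `strand`, `start`, `end` (0-based half-open).
#' @export
promoterWindows <- function(tss, width = 50L, L, circular = TRUE,
                            strands = NULL) {
  if (is(tss, "TSSCollection")) {
    pos <- tssPositions(tss); str <- tssStrands(tss)
  } else {
    pos <- as.integer(tss); str <- strands
  }
  if (length(pos) == 0L)
    return(data.frame(window_id = integer(0), tss_position = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  segs <- lapply(seq_along(pos), function(i) {
    w <- promoterWindow(pos[i], str[i], width, L, circular)
    data.frame(window_id = i, tss_position = pos[i], strand = str[i],
               start = as.integer(w$segments[, "start"]),
               end = as.integer(w$segments[, "end"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(segs, list(make.row.names = FALSE)))
}

# split site intervals into linear segments (wrapped sites give two)
.siteSegments <- function(sites, L = NULL) {
  if (nrow(sites) == 0L)
    return(data.frame(site_id = integer(0), start = integer(0),
                      end = integer(0)))
  stop0 <- sites$start + sites$span
  wraps <- !is.null(L) & stop0 > (L %||% Inf)
  segs <- lapply(seq_len(nrow(sites)), function(i) {
    if (wraps[i])
      data.frame(site_id = i, start = c(sites$start[i], 0L),
                 end = c(L, stop0[i] - L))
    else
      data.frame(site_id = i, start = sites$start[i], end = stop0[i])
  })
  do.call(rbind, c(segs, list(make.row.names = FALSE)))
}

#' Count overlaps between promoter windows and motif sites
#'
#' Counts (window, site) pairs that overlap under the chosen mode — "span"
#' (any base of the site interval falls inside a window segment, the
#' inclusive reading of a site's location) or "start" (only the site's
#' leftmost base is tested) — together with the number of windows hit by
#' at least one site. A pair overlapping a window in both wrapped segments
#' is counted once.
#'
#' @param windows Segment data frame from [promoterWindows()].
#' @param sites Site data frame from [scanGenome()].
#' @param L Genome length (needed to unwrap circular sites).
#' @param mode Overlap mode, "span" (default) or "start".
#' @return A list with `pairs` (overlapping pair count), `windowsHit`
#'   (windows with >= 1 site) and `hit` (logical per window).
#' @export
countWindowHits <- function(windows, sites, L = NULL,
                            mode = c("span", "start")) {
  mode <- match.arg(mode)
  nw <- if (nrow(windows)) max(windows$window_id) else 0L
  if (nrow(windows) == 0L || nrow(sites) == 0L)
    return(list(pairs = 0L, windowsHit = 0L, hit = logical(nw)))
  ss <- .siteSegments(sites, L)
  if (mode == "start") {
    ss <- data.frame(site_id = seq_len(nrow(sites)),
                     start = sites$start, end = sites$start + 1L)
  }
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(start = windows$start + 1L, end = windows$end),
    IRanges::IRanges(start = ss$start + 1L, end = ss$end))
  pairs <- unique(data.frame(
    w = windows$window_id[S4Vectors::queryHits(ov)],
    s = ss$site_id[S4Vectors::subjectHits(ov)]))
  hit <- logical(nw)
  hit[unique(pairs$w)] <- TRUE
  list(pairs = nrow(pairs), windowsHit = sum(hit), hit = hit)
}

#' Classify motif sites as genic or intergenic
#'
#' A site is genic iff its interval overlaps any annotated feature by at
#' least one base; sites wrapping the circular origin are unwrapped into
#' two segments before testing. The two counts partition the site list.
#'
#' @param sites Site data frame from [scanGenome()].
#' @param features Feature data frame from [readAnnotation()] (ORFs).
#' @param L Genome length (needed to unwrap circular sites).
#' @return A list with `nGenic`, `nIntergenic` and the per-site logical
#'   `genic`.
#' @export
classifySites <- function(sites, features, L = NULL) {
  if (nrow(sites) == 0L)
    return(list(nGenic = 0L, nIntergenic = 0L, genic = logical(0)))
  genic <- logical(nrow(sites))
  if (nrow(features) > 0L) {
    ss <- .siteSegments(sites, L)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = ss$start + 1L, end = ss$end),
      IRanges::IRanges(start = features$start + 1L, end = features$end))
    genic[unique(ss$site_id[S4Vectors::queryHits(ov)])] <- TRUE
  }
  list(nGenic = sum(genic), nIntergenic = sum(!genic), genic = genic)
}

#' Fraction of ORFs with a motif site in their putative promoter
#'
#' Takes the `width`-bp window upstream of each ORF's annotated 5' end
#' (the start coordinate for "+" ORFs, the end for "-" ORFs, strand-aware)
#' and returns the fraction of ORFs whose window contains at least one
#' site under the chosen overlap mode.
#'
#' @param features Feature data frame; only rows with `kind == "ORF"` are
#'   used.
#' @param sites Site data frame from [scanGenome()].
#' @param width Window width in bases (default 50).
#' @param L Genome length.
#' @param circular Logical topology flag.
#' @param mode Overlap mode passed to [countWindowHits()].
#' @return Proportion in [0, 1].
#' @export
promoterFraction <- function(features, sites, width = 50L, L,
                             circular = TRUE, mode = c("span", "start")) {
  mode <- match.arg(mode)
  orfs <- features[features$kind == "ORF", , drop = FALSE]
  if (nrow(orfs) == 0L) return(0)
  # TSS-equivalent anchor: the ORF's 5'-most base by strand
  anchor <- ifelse(orfs$strand == "+", orfs$start, orfs$end - 1L)
  win <- promoterWindows(as.integer(anchor), width = width, L = L,
                         circular = circular, strands = orfs$strand)
  countWindowHits(win, sites, L = L, mode = mode)$windowsHit / nrow(orfs)
}

#' Expected fraction of windows containing a motif start
#'
#' Under uniform i.i.d. bases, a motif with `k` specified positions starts
#' at a given position with probability \eqn{4^{-k}} (single orientation),
#' so a `w`-bp window is expected to contain a motif start with
#' probability approximately \eqn{w \cdot 4^{-k}} (capped at 1). For the
#' bipartite Type I motifs with 7 specified bases and 50 bp promoter
#' windows this gives \eqn{50/4^7 \approx 0.31\%}.
#'
#' @param k Number of specified (non-N) motif positions, >= 1.
#' @param w Window width in bases, >= 0.
#' @return Expected proportion in [0, 1].
#' @examples
#' expectedPromoterFraction(7, 50)  # ~0.00305
#' @export
expectedPromoterFraction <- function(k, w) {
  if (k < 1) stop("'k' must be >= 1")
  if (w < 0) stop("'w' must be >= 0")
  min(1, w * 4^(-k))
}

#' Per-motif context summary
#'
#' For each motif label present in `sites`, tabulates total sites, the
#' genic/intergenic split, the number of ORF promoter windows containing a
#' site, and the fraction of ORFs with a promoter site.
#'
#' @inheritParams promoterFraction
#' @param labels Motif labels to report on; defaults to those present in
#'   `sites`, but can be supplied so motifs without any site still get a
#'   (zero) row.
#' @return A data frame with one row per motif label and columns
#'   `motif_label`, `n_sites`, `n_genic`, `n_intergenic`,
#'   `n_promoter_hits`, `fraction_orfs_with_promoter_site`.
#' @export
contextSummary <- function(sites, features, width = 50L, L,
                           circular = TRUE, mode = c("span", "start"),
                           labels = unique(sites$motif_label)) {
  mode <- match.arg(mode)
  orfs <- features[features$kind == "ORF", , drop = FALSE]
  rows <- lapply(labels, function(lab) {
    s <- sites[sites$motif_label == lab, , drop = FALSE]
    cl <- classifySites(s, orfs, L = L)
    hits <- 0L
    if (nrow(orfs) > 0L) {
      anchor <- ifelse(orfs$strand == "+", orfs$start, orfs$end - 1L)
      win <- promoterWindows(as.integer(anchor), width = width, L = L,
                             circular = circular, strands = orfs$strand)
      hits <- countWindowHits(win, s, L = L, mode = mode)$windowsHit
    }
    data.frame(motif_label = lab, n_sites = nrow(s),
               n_genic = cl$nGenic, n_intergenic = cl$nIntergenic,
               n_promoter_hits = hits,
               fraction_orfs_with_promoter_site =
                 if (nrow(orfs)) hits / nrow(orfs) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
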