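# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the scanner oracle works on character
# sets, the overlap oracle enumerates covered bases, and the signed-rank
# oracle enumerates all sign assignments.

# allowed characters per motif position; N (spacer or literal) matches any
# base including genome N, specified positions never match N
motifCharSets <- function(motifText) {
  chars <- strsplit(motifText, "")[[1]]
  lapply(chars, function(ch) {
    if (ch == "N") c("A", "C", "G", "T", "N")
    else strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
  })
}

# naive sliding-window scan checking every position and both patterns
naiveScan <- function(genome, motif, circular = isCircular(genome)) {
  seqc <- strsplit(as.character(genomeSeq(genome)), "")[[1]]
  L <- length(seqc)
  span <- motifSpan(motif)
  ext <- if (circular) c(seqc, seqc[seq_len(span - 1)]) else seqc
  matchAt <- function(sets, s) {
    for (o in seq_along(sets)) {
      if (!(ext[s + o] %in% sets[[o]])) return(FALSE)
    }
    TRUE
  }
  fwdSets <- motifCharSets(motifString(motif))
  maxStart <- if (circular) L - 1L else L - span
  if (maxStart < 0L) return(integer(0))
  starts <- character(0)
  hits <- data.frame(start = integer(0), orientation = character(0))
  pal <- isPalindromic(motif)
  revSets <- if (!pal) motifCharSets(motifString(reverseComplement(motif)))
  for (s in 0:maxStart) {
    f <- matchAt(fwdSets, s)
    r <- if (pal) FALSE else matchAt(revSets, s)
    if (f) hits <- rbind(hits, data.frame(start = s, orientation = "+"))
    else if (r) hits <- rbind(hits, data.frame(start = s, orientation = "-"))
  }
  hits[order(hits$start, hits$orientation), , drop = FALSE]
}

# vectorized character-set oracle (membership tests on the letter vector;
# no bit masks), with its own dedup and ordering logic
charSetScan <- function(genome, motif, circular = isCircular(genome)) {
  seqc <- strsplit(as.character(genomeSeq(genome)), "")[[1]]
  L <- length(seqc)
  span <- motifSpan(motif)
  ext <- if (circular && span > 1) c(seqc, seqc[seq_len(span - 1)]) else seqc
  startsOf <- function(sets) {
    n <- length(ext) - span + 1L
    if (n < 1L) return(integer(0))
    ok <- rep(TRUE, n)
    for (o in seq_along(sets))
      ok <- ok & (ext[seq_len(n) + o - 1L] %in% sets[[o]])
    which(ok) - 1L
  }
  fwd <- startsOf(motifCharSets(motifString(motif)))
  if (isPalindromic(motif)) {
    keep <- fwd[fwd < L]
    return(data.frame(start = keep, orientation = rep("+", length(keep))))
  }
  rev <- startsOf(motifCharSets(motifString(reverseComplement(motif))))
  fwd <- fwd[fwd < L]; rev <- rev[rev < L]
  rev <- setdiff(rev, fwd)  # same physical duplex site: keep "+"
  out <- data.frame(start = c(fwd, rev),
                    orientation = c(rep("+", length(fwd)),
                                    rep("-", length(rev))))
  out[order(out$start, out$orientation), , drop = FALSE]
}

# all-pairs overlap count via explicit covered-base sets on the circle
bruteWindowHits <- function(windows, sites, L, mode = "span") {
  ids <- unique(windows$window_id)
  pairs <- 0L
  hitWindows <- 0L
  for (w in ids) {
    segs <- windows[windows$window_id == w, , drop = FALSE]
    covered <- unlist(lapply(seq_len(nrow(segs)), function(i)
      seq(segs$start[i], segs$end[i] - 1L)))
    hit <- FALSE
    for (s in seq_len(nrow(sites))) {
      siteBases <- if (mode == "span")
        (sites$start[s] + seq_len(sites$span[s]) - 1L) %% L
      else sites$start[s]
      if (any(siteBases %in% covered)) {
        pairs <- pairs + 1L
        hit <- TRUE
      }
    }
    if (hit) hitWindows <- hitWindows + 1L
  }
  list(pairs = pairs, windowsHit = hitWindows)
}

# exact two-sided signed-rank P by enumerating all 2^n sign assignments
enumSignedRankP <- function(values) {
  v <- values[values != 0]
  n <- length(v)
  if (n == 0) return(1)
  ranks <- rank(abs(v))
  W <- sum(ranks[v > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(signs, 1, function(s) sum(ranks[unlist(s)]))
  pLe <- mean(Ws <= W + 1e-9)
  pGe <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# random genome as a character string
randomSeq <- function(L, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), L, replace = TRUE, prob = probs),
        collapse = "")
}

# random bipartite motif with IUPAC letters in the half-sites
randomMotif <- function() {
  iupac <- c("A", "C", "G", "T", "W", "S", "R", "Y")
  h1 <- paste(sample(iupac, sample(2:4, 1), replace = TRUE,
                     prob = c(rep(4, 4), rep(1, 4))), collapse = "")
  h2 <- paste(sample(iupac, sample(2:4, 1), replace = TRUE,
                     prob = c(rep(4, 4), rep(1, 4))), collapse = "")
  k <- sample(0:8, 1)
  parseMotif(if (k == 0 && runif(1) < 0.3) h1
             else paste0(h1, "(N", k, ")", h2))
}
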