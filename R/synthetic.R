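#' @include enrichment.R
NULL

# run expr with a local RNG state seeded at `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# per-generator seed offsets, so each generator is reproducible on its own
.SEED_OFFSETS <- c(genome = 0L, annotation = 1L, tss = 2L, sites = 3L,
                   plant = 4L)

#' Describe a synthetic dataset with known ground truth
#'
#' Constructor for [SyntheticScenario-class]. Defaults describe the scale
#' used in calibration and power studies of the permutation test: a 100 kb
#' circular genome at 50% GC, 300 planted sites of the bipartite motif
#' `CCA(N7)CTTC`, 500 TSSs with 50 bp promoter windows, and no planted
#' TSS-site avoidance (the exact rotation null).
#'
#' @param L Genome length in bases.
#' @param gc GC proportion.
#' @param circular Topology flag.
#' @param motif A [BipartiteMotif-class] (or motif string to parse).
#' @param nSites Number of sites to plant.
#' @param nOrfs Number of non-overlapping ORFs.
#' @param orfLengthRange ORF length bounds in bases.
#' @param nTss Number of TSSs to draw.
#' @param width Promoter window width.
#' @param avoidProb Probability of rejecting a TSS draw whose window
#'   overlaps a site (0 = exact null; 0.9 plants strong depletion).
#' @param seed Integer seed for all generators.
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(L = 100000L, gc = 0.5, circular = TRUE,
                              motif = "CCA(N7)CTTC", nSites = 300L,
                              nOrfs = 40L, orfLengthRange = c(300L, 1500L),
                              nTss = 500L, width = 50L, avoidProb = 0,
                              seed = 1L) {
  if (is.character(motif)) motif <- parseMotif(motif)
  new("SyntheticScenario", L = as.integer(L), gc = as.numeric(gc),
      circular = isTRUE(circular), motif = motif,
      nSites = as.integer(nSites), nOrfs = as.integer(nOrfs),
      orfLengthRange = as.integer(orfLengthRange), nTss = as.integer(nTss),
      width = as.integer(width), avoidProb = as.numeric(avoidProb),
      seed = as.integer(seed))
}

#' Generate a random genome with i.i.d. bases
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2, reproducibly from the scenario seed.
#'
#' @param scenario A [SyntheticScenario-class].
#' @return A [Genome-class] with id `"synthetic"`.
#' @export
genGenome <- function(scenario) {
  probs <- c(A = (1 - scenario@gc) / 2, C = scenario@gc / 2,
             G = scenario@gc / 2, T = (1 - scenario@gc) / 2)
  bases <- .withSeed(scenario@seed + .SEED_OFFSETS[["genome"]],
                     sample(names(probs), scenario@L, replace = TRUE,
                            prob = probs))
  newGenome("synthetic", paste(bases, collapse = ""),
            circular = scenario@circular)
}

# one concrete realization of a motif (specified IUPAC positions sampled
# among their allowed bases, spacer positions uniform ACGT)
.realizeMotif <- function(motif) {
  chars <- strsplit(motifString(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    sample(allowed, 1L)
  }, character(1)), collapse = "")
}

#' Plant motif occurrences at known positions
#'
#' Writes one concrete realization of the motif (or of its reverse
#' complement, for "-" orientations) at each requested start, after
#' optionally scrubbing the background of chance occurrences. Scrubbing
#' iteratively resamples one specified-position base inside each
#' off-target occurrence (never touching a planted footprint) until the
#' scan finds exactly the planted set, within a bounded number of rounds.
#' Planted positions must not overlap each other.
#'
#' @param genome A [Genome-class].
#' @param motif A [BipartiteMotif-class].
#' @param positions Integer vector of 0-based planting starts (must leave
#'   room for the motif span; on circular genomes they may wrap).
#' @param orientations "+" or "-" per position (recycled).
#' @param scrub Remove chance occurrences outside the planted set.
#' @param maxRounds Bound on scrub iterations.
#' @param seed Seed for realization and scrubbing draws.
#' @return A [Genome-class] whose scan yields exactly the planted sites
#'   (when `scrub = TRUE`).
#' @export
plantMotifs <- function(genome, motif, positions, orientations = "+",
                        scrub = TRUE, maxRounds = 100L, seed = 1L) {
  L <- genomeLength(genome)
  span <- motifSpan(motif)
  positions <- as.integer(positions)
  orientations <- rep(orientations, length.out = length(positions))
  circ <- isCircular(genome)
  if (!circ && any(positions + span > L))
    stop("planted positions leave no room for the motif span")
  if (any(positions < 0L) || any(positions >= L))
    stop("planted positions must lie in [0, L)")
  # overlap check on the circle
  if (length(positions) > 1L) {
    o <- order(positions)
    p <- positions[o]
    gaps <- c(diff(p), p[1L] + L - p[length(p)])
    if (any(gaps < span)) stop("planted positions overlap each other")
  }
  .withSeed(seed + .SEED_OFFSETS[["plant"]], {
    chars <- strsplit(as.character(genomeSeq(genome)), "")[[1]]
    footprint <- logical(L)
    for (i in seq_along(positions)) {
      word <- if (orientations[i] == "+") .realizeMotif(motif) else
        as.character(Biostrings::reverseComplement(
          DNAString(.realizeMotif(motif))))
      idx <- (positions[i] + seq_len(span) - 1L) %% L + 1L
      chars[idx] <- strsplit(word, "")[[1]]
      footprint[idx] <- TRUE
    }
    if (scrub) {
      specified <- which(!is.na(.patternBits(motif)))
      for (round in seq_len(maxRounds)) {
        g <- newGenome(genomeId(genome), paste(chars, collapse = ""),
                       circular = circ)
        found <- scanGenome(g, motif)
        off <- setdiff(found$start, positions)
        if (length(off) == 0L) break
        if (round == maxRounds)
          stop("could not scrub chance occurrences within ", maxRounds,
               " rounds")
        for (s in off) {
          # mutate one specified-position base outside planted footprints
          cand <- (s + specified - 1L) %% L + 1L
          cand <- cand[!footprint[cand]]
          if (length(cand) == 0L)
            stop("off-target occurrence at ", s,
                 " lies entirely within planted footprints")
          j <- if (length(cand) == 1L) cand else sample(cand, 1L)
          chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
        }
      }
    }
    newGenome(genomeId(genome), paste(chars, collapse = ""),
              circular = circ)
  })
}

#' Draw non-overlapping site positions without a sequence
#'
#' Positions-only counterpart of planting: draws `n` non-overlapping
#' duplex site starts uniformly on a circular genome and returns them as a
#' site data frame. Calibration and power studies of the permutation test
#' operate on positions, so they use this fast path; the full
#' sequence-level round trip (plant, scan, recover) is exercised
#' separately.
#'
#' @param L Genome length.
#' @param n Number of sites.
#' @param span Site span in bases.
#' @param motifLabel Label for the site rows.
#' @param genomeId Genome id for the site rows.
#' @param seed Integer seed.
#' @return A site data frame as produced by [scanGenome()].
#' @export
randomSites <- function(L, n, span, motifLabel = "synthetic",
                        genomeId = "synthetic", seed = 1L) {
  L <- as.integer(L); n <- as.integer(n); span <- as.integer(span)
  if (n * span > L) stop("cannot fit ", n, " non-overlapping sites")
  if (n == 0L)
    return(data.frame(genome_id = character(0), start = integer(0),
                      span = integer(0), orientation = character(0),
                      motif_label = character(0), stringsAsFactors = FALSE))
  # gap-insertion construction: sorted distinct draws from the reduced
  # space, spread out by span-1, give pairwise gaps >= span (also across
  # the circular origin)
  starts <- .withSeed(seed + .SEED_OFFSETS[["sites"]], {
    m <- L - n * span + n  # size of the reduced sampling space
    if (m < n) stop("cannot fit ", n, " non-overlapping sites")
    u <- sort(sample.int(m, n) - 1L)
    u + (seq_len(n) - 1L) * (span - 1L)
  })
  data.frame(genome_id = genomeId, start = starts, span = span,
             orientation = "+", motif_label = motifLabel,
             stringsAsFactors = FALSE)
}

#' Generate a TSS collection, optionally avoiding motif sites
#'
#' Each TSS position (and strand) is drawn uniformly; with probability
#' `avoidProb` a draw whose upstream promoter window would overlap a site
#' is rejected and redrawn (bounded retries). `avoidProb = 0` makes TSS
#' placement independent of the sites — the exact rotation null —
#' while values near 1 plant a depletion signal of known strength.
#' Rejection sampling (rather than post-hoc filtering) keeps the marginal
#' TSS distribution near-uniform, so the rotation null stays approximately
#' valid under the alternative.
#'
#' @param scenario A [SyntheticScenario-class].
#' @param sites Site data frame ([scanGenome()] or [randomSites()]).
#' @param maxRetries Bound on redraws per TSS.
#' @return A [TSSCollection-class] with source `"synthetic"`.
#' @export
genTss <- function(scenario, sites, maxRetries = 1000L) {
  L <- scenario@L
  groups <- .siteGroups(sites)
  overlaps <- function(pos, strand) {
    lo <- .windowLo(pos, strand, scenario@width)
    hit <- FALSE
    for (g in groups) {
      if (.circIntervalCount(g$S, (lo - g$ext) %% L,
                             scenario@width + g$ext, L) > 0L) {
        hit <- TRUE; break
      }
    }
    hit
  }
  .withSeed(scenario@seed + .SEED_OFFSETS[["tss"]], {
    pos <- integer(scenario@nTss)
    str <- character(scenario@nTss)
    for (i in seq_len(scenario@nTss)) {
      for (try in seq_len(maxRetries)) {
        p <- sample.int(L, 1L) - 1L
        s <- sample(c("+", "-"), 1L)
        if (scenario@avoidProb > 0 && overlaps(p, s) &&
            runif(1) < scenario@avoidProb) next
        pos[i] <- p; str[i] <- s
        break
      }
      if (try == maxRetries && !nzchar(str[i]))
        stop("TSS retry budget exhausted: genome saturated with sites")
    }
    newTssCollection("synthetic", pos, str, "synthetic")
  })
}

# sorted site-start groups by span, shared by genTss
.siteGroups <- function(sites) {
  bySpan <- split(sites$start, sites$span)
  lapply(names(bySpan), function(k)
    list(S = sort(as.integer(bySpan[[k]])), ext = as.integer(k) - 1L))
}

# count of sorted starts S inside circular interval [a, a+len) on [0, L)
.circIntervalCount <- function(S, a, len, L) {
  n <- length(S)
  if (n == 0L) return(0L)
  if (len >= L) return(n)
  b <- a + len
  cLTa <- findInterval(a - 0.5, S)
  if (b <= L) return(findInterval(b - 0.5, S) - cLTa)
  (n - cLTa) + findInterval(b - L - 0.5, S)
}

#' Generate a non-overlapping ORF annotation
#'
#' Places `nOrfs` features with lengths uniform on `orfLengthRange` and
#' random strands, rejection-sampling starts until no two overlap (the
#' genome end is respected on linear genomes; features never wrap).
#'
#' @param scenario A [SyntheticScenario-class].
#' @param maxRetries Bound on placement attempts per ORF.
#' @return A feature data frame as produced by [readAnnotation()].
#' @export
genAnnotation <- function(scenario, maxRetries = 1000L) {
  L <- scenario@L
  n <- scenario@nOrfs
  if (n == 0L)
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  if (n * max(scenario@orfLengthRange) > L)
    stop("infeasible packing: ORFs cannot fit in the genome")
  .withSeed(scenario@seed + .SEED_OFFSETS[["annotation"]], {
    lens <- sample(seq(scenario@orfLengthRange[1L],
                       scenario@orfLengthRange[2L]), n, replace = TRUE)
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(maxRetries)) {
        s <- sample.int(L - lens[i] + 1L, 1L) - 1L
        e <- s + lens[i]
        if (!any(s < ends & e > starts)) {
          starts <- c(starts, s); ends <- c(ends, e)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible packing: retry budget exhausted")
    }
    o <- order(starts)
    data.frame(genome_id = "synthetic", start = starts[o], end = ends[o],
               strand = sample(c("+", "-"), n, replace = TRUE),
               kind = "ORF", name = paste0("orf", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' Materialize a synthetic scenario as a file set
#'
#' Generates the genome (with planted sites), annotation and TSS table for
#' a scenario and writes them in the formats the readers consume (FASTA,
#' GFF3, TSV), together with a JSON ground-truth record (planted site
#' starts, scenario parameters).
#'
#' @param scenario A [SyntheticScenario-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulateScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  span <- motifSpan(scenario@motif)
  sites <- randomSites(scenario@L, scenario@nSites, span,
                       motifLabel = motifLabel(scenario@motif),
                       seed = scenario@seed)
  genome <- plantMotifs(genGenome(scenario), scenario@motif, sites$start,
                        seed = scenario@seed)
  ann <- genAnnotation(scenario)
  tss <- genTss(scenario, sites)
  paths <- list(fasta = file.path(dir, "genome.fasta"),
                gff3 = file.path(dir, "annotation.gff3"),
                tss = file.path(dir, "tss.tsv"),
                truth = file.path(dir, "truth.json"))
  writeFasta(genome, paths$fasta)
  writeAnnotation(ann, paths$gff3, "gff3")
  writeTssTable(tss, paths$tss)
  jsonlite::write_json(
    list(L = scenario@L, gc = scenario@gc, circular = scenario@circular,
         motif = motifString(scenario@motif),
         planted_starts = sites$start, n_tss = scenario@nTss,
         width = scenario@width, avoid_prob = scenario@avoidProb,
         seed = scenario@seed),
    paths$truth, auto_unbox = TRUE)
  invisible(list(genome = genome, sites = sites, annotation = ann,
                 tss = tss, paths = paths))
}
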