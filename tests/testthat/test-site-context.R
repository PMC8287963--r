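test_that("promoter windows follow the strand-aware upstream definition", {
  w <- promoterWindow(999L, "+", 50L, 1000000L, circular = FALSE)
  expect_equal(unname(w$segments), cbind(949L, 999L), ignore_attr = TRUE)
  expect_equal(w$covered, 50L)

  w <- promoterWindow(9L, "+", 50L, 100L, circular = TRUE)
  expect_equal(w$segments[, "start"], c(59, 0))
  expect_equal(w$segments[, "end"], c(100, 9))
  expect_equal(w$covered, 50L)

  w <- promoterWindow(9L, "-", 50L, 1000000L, circular = FALSE)
  expect_equal(unname(w$segments), cbind(10L, 60L), ignore_attr = TRUE)

  # linear truncation at the left boundary
  w <- promoterWindow(9L, "+", 50L, 100L, circular = FALSE)
  expect_true(w$truncated)
  expect_equal(w$covered, 9L)

  expect_error(promoterWindow(10L, "+", 100L, 100L, circular = TRUE),
               "width")
  expect_error(promoterWindow(-1L, "+", 10L, 100L), "tssPosition")
})

test_that("window hit counting matches the all-pairs brute-force oracle", {
  set.seed(21)
  for (rep in 1:12) {
    L <- sample(500:20000, 1)
    nTss <- sample(5:40, 1)
    nSites <- sample(0:60, 1)
    width <- sample(10:80, 1)
    tssPos <- sample(0:(L - 1), nTss)
    tssStr <- sample(c("+", "-"), nTss, replace = TRUE)
    span <- sample(c(4L, 13L, 14L), 1)
    sites <- data.frame(
      genome_id = "g",
      start = if (nSites) sample(0:(L - 1), nSites, replace = TRUE)
              else integer(0),
      span = span, orientation = "+", motif_label = "m",
      stringsAsFactors = FALSE)
    win <- promoterWindows(tssPos, width = width, L = L, circular = TRUE,
                           strands = tssStr)
    for (mode in c("span", "start")) {
      got <- countWindowHits(win, sites, L = L, mode = mode)
      want <- bruteWindowHits(win, sites, L, mode = mode)
      expect_equal(got$pairs, want$pairs, info = paste(rep, mode))
      expect_equal(got$windowsHit, want$windowsHit,
                   info = paste(rep, mode))
    }
  }
})

test_that("start-mode hits never exceed span-mode hits", {
  set.seed(22)
  for (rep in 1:8) {
    L <- 5000L
    win <- promoterWindows(sample(0:(L - 1), 20), width = 50, L = L,
                           circular = TRUE,
                           strands = sample(c("+", "-"), 20, TRUE))
    sites <- data.frame(genome_id = "g",
                        start = sample(0:(L - 1), 40, TRUE), span = 14L,
                        orientation = "+", motif_label = "m")
    expect_lte(countWindowHits(win, sites, L, mode = "start")$pairs,
               countWindowHits(win, sites, L, mode = "span")$pairs)
  }
})

test_that("window hit counts are equivariant under genome mirroring", {
  set.seed(23)
  L <- 4000L
  for (rep in 1:6) {
    pos <- sample(0:(L - 1), 15)
    str <- sample(c("+", "-"), 15, TRUE)
    sites <- data.frame(genome_id = "g",
                        start = sample(0:(L - 1), 30), span = 10L,
                        orientation = "+", motif_label = "m")
    win <- promoterWindows(pos, width = 40, L = L, circular = TRUE,
                           strands = str)
    # mirror: x -> L-1-x flips strands and maps site [s, s+sp) to
    # [L-s-sp, L-s)
    mpos <- (L - 1L - pos) %% L
    mstr <- ifelse(str == "+", "-", "+")
    msites <- sites
    msites$start <- (L - sites$start - sites$span) %% L
    mwin <- promoterWindows(mpos, width = 40, L = L, circular = TRUE,
                            strands = mstr)
    expect_equal(countWindowHits(win, sites, L)$pairs,
                 countWindowHits(mwin, msites, L)$pairs)
    expect_equal(countWindowHits(win, sites, L)$windowsHit,
                 countWindowHits(mwin, msites, L)$windowsHit)
  }
})

test_that("sites classify as genic or intergenic by any-base overlap", {
  feats <- data.frame(genome_id = "g", start = c(100L, 400L),
                      end = c(200L, 600L), strand = "+", kind = "ORF",
                      name = c("a", "b"))
  sites <- data.frame(genome_id = "g",
                      start = c(150L, 250L, 195L, 595L), span = 10L,
                      orientation = "+", motif_label = "m")
  cl <- classifySites(sites, feats, L = 1000L)
  expect_equal(cl$genic, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(cl$nGenic + cl$nIntergenic, nrow(sites))
})

test_that("classification is invariant to feature order and splitting", {
  set.seed(24)
  L <- 10000L
  feats <- data.frame(genome_id = "g",
                      start = c(1000L, 3000L, 7000L),
                      end = c(2000L, 5000L, 9000L), strand = "+",
                      kind = "ORF", name = c("a", "b", "c"))
  sites <- data.frame(genome_id = "g", start = sample(0:(L - 15), 80),
                      span = 14L, orientation = "+", motif_label = "m")
  base <- classifySites(sites, feats, L)$genic
  shuffled <- classifySites(sites, feats[c(3, 1, 2), ], L)$genic
  expect_equal(shuffled, base)
  # split feature b into two abutting halves
  split <- rbind(feats[1, ],
                 data.frame(genome_id = "g", start = 3000L, end = 4000L,
                            strand = "+", kind = "ORF", name = "b1"),
                 data.frame(genome_id = "g", start = 4000L, end = 5000L,
                            strand = "+", kind = "ORF", name = "b2"),
                 feats[3, ])
  expect_equal(classifySites(sites, split, L)$genic, base)
})

test_that("sites wrapping the circular origin are classified unwrapped", {
  feats <- data.frame(genome_id = "g", start = 0L, end = 50L,
                      strand = "+", kind = "ORF", name = "a")
  wrapSite <- data.frame(genome_id = "g", start = 995L, span = 10L,
                         orientation = "+", motif_label = "m")
  expect_equal(classifySites(wrapSite, feats, L = 1000L)$nGenic, 1L)
})

test_that("promoter fraction has the right endpoints", {
  feats <- data.frame(genome_id = "g",
                      start = seq(100L, 900L, by = 200L) ,
                      end = seq(100L, 900L, by = 200L) + 100L,
                      strand = "+", kind = "ORF",
                      name = paste0("o", 1:5))
  noSites <- data.frame(genome_id = character(0), start = integer(0),
                        span = integer(0), orientation = character(0),
                        motif_label = character(0))
  expect_equal(promoterFraction(feats, noSites, width = 50, L = 1000L), 0)
  # one site planted in each upstream window
  planted <- data.frame(genome_id = "g", start = feats$start - 20L,
                        span = 10L, orientation = "+", motif_label = "m")
  expect_equal(promoterFraction(feats, planted, width = 50, L = 1000L), 1)
})

test_that("promoter fraction on an i.i.d. genome matches the analytic rate", {
  set.seed(25)
  # palindromic motif with 6 specified bases so the duplex scan equals the
  # single-orientation count the analytic expectation assumes
  m <- parseMotif("CCA(N1)TGG")
  expect_true(isPalindromic(m))
  k <- specifiedBases(m)
  nOrfs <- 3000L
  L <- nOrfs * 60L
  g <- newGenome("g", randomSeq(L, gc = 0.5))
  sites <- scanGenome(g, m)
  feats <- data.frame(genome_id = "g", start = seq_len(nOrfs) * 60L - 10L,
                      end = seq_len(nOrfs) * 60L, strand = "+",
                      kind = "ORF", name = paste0("o", seq_len(nOrfs)))
  frac <- promoterFraction(feats, sites, width = 50, L = L,
                           mode = "start")
  expected <- expectedPromoterFraction(k, 50)
  se <- sqrt(expected * (1 - expected) / nOrfs)
  expect_lt(abs(frac - expected), 4 * se + 1e-9)
})

test_that("the analytic promoter expectation behaves at the boundaries", {
  expect_equal(expectedPromoterFraction(7, 50), 50 / 4^7)
  expect_equal(expectedPromoterFraction(5, 0), 0)
  expect_equal(expectedPromoterFraction(1, 4), 1)
  expect_error(expectedPromoterFraction(0, 50), "k")
})

test_that("context summaries partition sites and count promoter hits", {
  set.seed(26)
  L <- 20000L
  m <- parseMotif("CCA(N7)CTTC")
  g <- plantMotifs(newGenome("g", randomSeq(L)), m,
                   positions = c(1000L, 5000L, 15000L), seed = 3L)
  sites <- scanGenome(g, m)
  feats <- data.frame(genome_id = "g", start = c(900L, 6000L),
                      end = c(1500L, 8000L), strand = "+", kind = "ORF",
                      name = c("a", "b"))
  cs <- contextSummary(sites, feats, width = 50, L = L)
  expect_equal(cs$n_sites, 3L)
  expect_equal(cs$n_genic + cs$n_intergenic, cs$n_sites)
  expect_equal(cs$n_genic, 1L)
  expect_true(cs$fraction_orfs_with_promoter_site >= 0 &&
              cs$fraction_orfs_with_promoter_site <= 1)
})
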