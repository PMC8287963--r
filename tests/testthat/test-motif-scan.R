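test_that("bipartite notation parses with decorations and plain words", {
  m <- parseMotif("5′-CCA(N7)CTTC-3′")
  expect_equal(m@half1, "CCA")
  expect_equal(spacerLength(m), 7L)
  expect_equal(m@half2, "CTTC")
  expect_equal(motifSpan(m), 14L)
  expect_equal(specifiedBases(m), 7L)

  m2 <- parseMotif("AAC(N6)GTGC")
  expect_equal(motifSpan(m2), 13L)
  expect_equal(specifiedBases(m2), 7L)

  gatc <- parseMotif("GATC")
  expect_equal(motifSpan(gatc), 4L)
  expect_equal(spacerLength(gatc), 0L)
  expect_true(isPalindromic(gatc))
  expect_true(isPalindromic(parseMotif("CCWGG")))
  expect_false(isPalindromic(parseMotif("CCA(N7)CTTC")))

  expect_error(parseMotif("CXA(N7)CTTC"), "IUPAC|parse")
  expect_error(parseMotif("CCA(N)CTTC"), "parse")
  expect_error(parseMotif("CCA(7)CTTC"), "parse")
})

test_that("motif reverse complement is IUPAC-aware and involutive", {
  rc <- reverseComplement(parseMotif("CCA(N7)CTTC"))
  expect_equal(motifString(rc), "GAAGNNNNNNNTGG")
  expect_equal(motifString(reverseComplement(parseMotif("GATC"))), "GATC")
  expect_equal(motifString(reverseComplement(parseMotif("CCWGG"))),
               "CCWGG")
  set.seed(42)
  for (i in 1:25) {
    m <- randomMotif()
    expect_equal(motifString(reverseComplement(reverseComplement(m))),
                 motifString(m))
  }
})

test_that("single planted instances are found with the right orientation", {
  m <- parseMotif("CCA(N7)CTTC")
  s <- scanGenome(newGenome("g", "CCAAAAAAAACTTC", circular = FALSE), m)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 0L)
  expect_equal(s$orientation, "+")

  s <- scanGenome(newGenome("g", "GAAGTTTTTTTTGG", circular = FALSE), m)
  expect_equal(s$start, 0L)
  expect_equal(s$orientation, "-")

  s <- scanGenome(newGenome("g", "GATC", circular = FALSE),
                  parseMotif("GATC"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$orientation, "+")

  expect_error(scanGenome(newGenome("g", "ACGT", circular = FALSE), m),
               "span")
})

test_that("scanner equals the naive sliding-window oracle on random genomes", {
  set.seed(7)
  motifs <- c(lapply(c("CCA(N7)CTTC", "AAC(N6)GTGC", "GAG(N7)GTCA",
                       "GATC", "CCWGG"), parseMotif),
              lapply(1:5, function(i) randomMotif()))
  for (i in 1:20) {
    L <- sample(200:4000, 1)
    circ <- i %% 2 == 0
    g <- newGenome(paste0("g", i), randomSeq(L, gc = runif(1, 0.3, 0.7)),
                   circular = circ)
    m <- motifs[[sample(length(motifs), 1)]]
    got <- scanGenome(g, m)
    want <- naiveScan(g, m)
    expect_equal(got$start, want$start, info = paste("genome", i))
    expect_equal(got$orientation, want$orientation,
                 info = paste("genome", i))
  }
})

test_that("circular site counts are invariant under genome rotation", {
  set.seed(8)
  seqc <- randomSeq(5000, gc = 0.45)
  m <- parseMotif("AAC(N6)GTGC")
  base <- nrow(scanGenome(newGenome("g", seqc), m))
  for (off in c(1, 137, 2500, 4999)) {
    rot <- paste0(substr(seqc, off + 1, 5000), substr(seqc, 1, off))
    expect_equal(nrow(scanGenome(newGenome("g", rot), m)), base)
  }
})

test_that("reverse-complementing the genome mirrors starts and swaps strands", {
  set.seed(9)
  L <- 3000
  seqc <- randomSeq(L)
  m <- parseMotif("GAG(N7)GTCA")
  g <- newGenome("g", seqc, circular = FALSE)
  grc <- newGenome("g", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seqc))),
    circular = FALSE)
  a <- scanGenome(g, m)
  b <- scanGenome(grc, m)
  expect_equal(nrow(a), nrow(b))
  span <- motifSpan(m)
  mapped <- sort(L - (a$start + span))
  expect_equal(sort(b$start), mapped)
  expect_equal(sum(a$orientation == "+"), sum(b$orientation == "-"))
})

test_that("genome N bases never match specified positions but match spacers", {
  m <- parseMotif("CCA(N7)CTTC")
  # N inside the spacer: still a site
  g <- newGenome("g", "CCANNNNNNNCTTC", circular = FALSE)
  expect_equal(nrow(scanGenome(g, m)), 1L)
  # N inside a specified half: no site
  g2 <- newGenome("g", "CCNAAAAAAACTTC", circular = FALSE)
  expect_equal(nrow(scanGenome(g2, m)), 0L)
})

test_that("duplex counts on uniform genomes match the closed-form rate", {
  set.seed(10)
  L <- 500000
  g <- newGenome("g", randomSeq(L, gc = 0.5))
  # non-palindromic, 7 specified bases: expect ~ 2 L / 4^7, sd ~ sqrt
  n <- nrow(scanGenome(g, parseMotif("AAC(N6)GTGC")))
  expected <- 2 * L * 4^-7
  expect_lt(abs(n - expected), 5 * sqrt(expected))
  # palindromic GATC: expect ~ L / 4^4
  n2 <- nrow(scanGenome(g, parseMotif("GATC")))
  expected2 <- L * 4^-4
  expect_lt(abs(n2 - expected2), 5 * sqrt(expected2))
})

test_that("countSites sums across records and supports chromosome-only mode", {
  set.seed(12)
  m <- parseMotif("CCA(N7)CTTC")
  chr <- plantMotifs(newGenome("chr", randomSeq(20000)), m,
                     positions = c(100L, 5000L, 12000L), seed = 1L)
  pls <- plantMotifs(newGenome("pls", randomSeq(3000)), m,
                     positions = 500L, seed = 2L)
  both <- countSites(list(chr, pls), m)
  expect_equal(both$count, 4L)
  chrOnly <- countSites(list(chr, pls), m, restrictToLargest = TRUE)
  expect_equal(chrOnly$count, 3L)
  per <- attr(both, "perRecord")
  expect_equal(unname(per["CCA(N7)CTTC", ]), c(3L, 1L))
  # absent motif
  expect_equal(countSites(newGenome("g", strrep("A", 1000)),
                          parseMotif("GATC"))$count, 0L)
})
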