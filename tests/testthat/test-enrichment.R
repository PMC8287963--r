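test_that("circular shifts are rigid, modular and invertible", {
  tss <- newTssCollection("g", c(10L, 20L), c("+", "-"))
  expect_equal(tssPositions(circularShift(tss, 5L, 100L)), c(15L, 25L))
  expect_equal(tssPositions(circularShift(tss, 100L, 100L)), c(10L, 20L))
  expect_equal(tssStrands(circularShift(tss, 5L, 100L)), c("+", "-"))
  # composition delta then L - delta restores the original
  set.seed(31)
  pos <- sample(0:999, 50)
  t0 <- newTssCollection("g", pos, rep("+", 50))
  for (delta in c(1L, 400L, 999L)) {
    back <- circularShift(circularShift(t0, delta, 1000L),
                          1000L - delta, 1000L)
    expect_equal(tssPositions(back), pos)
  }
  expect_error(circularShift(tss, 0L, 100L), "delta")
  expect_error(circularShift(tss, 101L, 100L), "delta")
})

test_that("permutation results are reproducible and tie-consistent", {
  set.seed(32)
  L <- 30000L
  sites <- randomSites(L, 60L, 14L, seed = 5L)
  tss <- newTssCollection("synthetic", sample(0:(L - 1), 100),
                          sample(c("+", "-"), 100, TRUE))
  a <- runPermutation(sites, tss, L, width = 50, B = 300, seed = 9L)
  b <- runPermutation(sites, tss, L, width = 50, B = 300, seed = 9L)
  expect_identical(nullCounts(a), nullCounts(b))
  expect_identical(pDepletion(a), pDepletion(b))
  expect_gte(a@kLe + a@kGe, a@B)
  expect_gte(pDepletion(a) + pEnrichment(a), 1 + 1 / (a@B + 1))
})

test_that("zero sites anywhere gives a degenerate all-tie null", {
  tss <- newTssCollection("synthetic", c(10L, 500L), c("+", "-"))
  noSites <- data.frame(genome_id = character(0), start = integer(0),
                        span = integer(0), orientation = character(0),
                        motif_label = character(0))
  r <- runPermutation(noSites, tss, L = 1000L, width = 50, B = 100,
                      seed = 1L)
  expect_equal(observedHits(r), 0L)
  expect_true(all(nullCounts(r) == 0L))
  expect_equal(pDepletion(r), 1)
})

test_that("the observed statistic agrees with the window-overlap counter", {
  set.seed(33)
  for (rep in 1:6) {
    L <- sample(2000:20000, 1)
    sites <- randomSites(L, sample(10:80, 1), sample(c(4L, 14L), 1),
                         seed = rep)
    n <- sample(10:60, 1)
    tss <- newTssCollection("synthetic", sample(0:(L - 1), n),
                            sample(c("+", "-"), n, TRUE))
    win <- promoterWindows(tss, width = 50, L = L, circular = TRUE)
    for (mode in c("span", "start")) {
      for (stat in c("windows", "pairs")) {
        r <- runPermutation(sites, tss, L, width = 50, B = 1,
                            seed = 1L, mode = mode, statistic = stat)
        want <- countWindowHits(win, sites, L = L, mode = mode)
        expect_equal(observedHits(r),
                     if (stat == "windows") want$windowsHit
                     else want$pairs,
                     info = paste(rep, mode, stat))
      }
    }
  }
})

test_that("null counts equal explicit TSS shifts and the rotation duality", {
  set.seed(34)
  L <- 5000L
  sites <- randomSites(L, 30L, 14L, seed = 2L)
  tss <- newTssCollection("synthetic", sample(0:(L - 1), 25),
                          sample(c("+", "-"), 25, TRUE))
  r <- runPermutation(sites, tss, L, width = 50, B = 20, seed = 7L)
  # reconstruct the delta stream and recount through the slow path
  set.seed(7L)
  deltas <- sample.int(L, 20, replace = TRUE)
  for (i in seq_along(deltas)) {
    shifted <- circularShift(tss, deltas[i], L)
    win <- promoterWindows(shifted, width = 50, L = L, circular = TRUE)
    expect_equal(nullCounts(r)[i],
                 countWindowHits(win, sites, L = L)$windowsHit,
                 info = paste("replicate", i))
    # rotation duality: shifting sites by L - delta instead of the TSSs
    dualSites <- sites
    dualSites$start <- (sites$start + (L - deltas[i])) %% L
    win0 <- promoterWindows(tss, width = 50, L = L, circular = TRUE)
    expect_equal(nullCounts(r)[i],
                 countWindowHits(win0, dualSites, L = L)$windowsHit,
                 info = paste("dual", i))
  }
})

test_that("exhaustive enumeration on a toy genome gives exact fractions", {
  L <- 20L
  sites <- data.frame(genome_id = "g", start = 3L, span = 4L,
                      orientation = "+", motif_label = "m")
  tss <- newTssCollection("g", 10L, "+")
  r <- runPermutation(sites, tss, L, width = 5, seed = 1L,
                      exhaustive = TRUE)
  expect_equal(r@B, L)
  # oracle: enumerate the 20 shifts explicitly
  counts <- vapply(1:L, function(d) {
    win <- promoterWindows(circularShift(tss, d, L), width = 5, L = L,
                           circular = TRUE)
    countWindowHits(win, sites, L = L)$windowsHit
  }, integer(1))
  expect_equal(sort(nullCounts(r)), sort(counts))
  expect_equal(pDepletion(r), mean(counts <= observedHits(r)))
  expect_equal(pEnrichment(r), mean(counts >= observedHits(r)))
})

test_that("empty TSS collections warn and return a zero observation", {
  sites <- data.frame(genome_id = "g", start = 3L, span = 4L,
                      orientation = "+", motif_label = "m")
  tss <- newTssCollection("g", integer(0), character(0))
  expect_warning(r <- runPermutation(sites, tss, L = 100L, width = 10,
                                     B = 10, seed = 1L), "empty")
  expect_equal(observedHits(r), 0L)
})

test_that("mismatched genomes and runaway costs are refused", {
  sites <- data.frame(genome_id = "a", start = 3L, span = 4L,
                      orientation = "+", motif_label = "m")
  tss <- newTssCollection("b", 10L, "+")
  expect_error(runPermutation(sites, tss, L = 100L, B = 10, width = 10),
               "different genomes")
  tss2 <- newTssCollection("a", 10L, "+")
  expect_error(runPermutation(sites, tss2, L = 100L, B = 10, width = 10,
                              maxCost = 5), "maxCost")
})

test_that("Bonferroni adjustment scales, caps and preserves order", {
  expect_equal(bonferroniAdjust(0.01, m = 5), 0.05)
  expect_equal(bonferroniAdjust(0.5, m = 10), 1)
  set.seed(35)
  p <- sort(runif(20))
  adj <- bonferroniAdjust(p, m = 25)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_error(bonferroniAdjust(c(0, 0.5)), "0, 1")
  expect_error(bonferroniAdjust(rep(0.1, 5), m = 3), "at least")
})
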