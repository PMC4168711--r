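test_that("the toy generator reproduces the single-nucleosome scenario", {
  fr <- simulateToy(seed = 4)
  expect_length(fr, 20L)
  expect_true(all(width(fr) == 146L))
  # identical seeds give byte-identical fragments
  expect_identical(as.data.frame(fr), as.data.frame(simulateToy(seed = 4)))
  # zero spread puts every midpoint on the centre
  fr0 <- simulateToy(sd = 0, seed = 1)
  expect_true(all(start(fr0) - 1 + width(fr0) / 2 == 300))
  # law of large numbers: the empirical mean midpoint approaches the centre
  frBig <- simulateToy(nReads = 1e5, seed = 2)
  expect_lte(abs(mean(start(frBig) - 1 + width(frBig) / 2) - 300), 1)
})

test_that("the map generator places well-positioned nucleosomes on the grid", {
  sim <- syntheticNucleosomeMap(wpNum = 30, wpDel = 0, fuzNum = 0, seed = 3)
  cen <- trueCenters(sim$map)
  expect_length(cen, 30L)
  expect_equal(diff(cen), rep(167, 29))            # 147 + 20 bp periodicity
  expect_equal(cen[1], 20 + 147 / 2)
  # deletions remove grid points; fuzzy nucleosomes are off-grid extras
  sim2 <- syntheticNucleosomeMap(wpNum = 30, wpDel = 5, fuzNum = 4, seed = 3)
  df <- sim2$map@nucleosomes
  expect_equal(sum(df$kind == "well"), 25L)
  expect_equal(sum(df$kind == "fuzzy"), 4L)
  expect_equal(unique(df$sd[df$kind == "well"]), 30)
  expect_equal(unique(df$sd[df$kind == "fuzzy"]), 50)
  expect_error(syntheticNucleosomeMap(wpNum = 10, wpDel = 11), "wpDel")
})

test_that("generated reads are reproducible and respect the coverage bound", {
  simA <- syntheticNucleosomeMap(wpNum = 25, wpDel = 2, seed = 8)
  simB <- syntheticNucleosomeMap(wpNum = 25, wpDel = 2, seed = 8)
  expect_identical(as.data.frame(simA$fragments),
                   as.data.frame(simB$fragments))
  expect_true(all(width(simA$fragments) == 147L))
  # fuzzy-free maps: per-base coverage stays within sampling slack of maxCover
  cov <- max(coverage(simA$fragments)[[1]])
  expect_lte(cov, 1.2 * 70)
})

test_that("positioning errors match calls to truths greedily and uniquely", {
  mkTruth <- function(cen) new("SyntheticMap",
    nucleosomes = S4Vectors::DataFrame(center = cen,
      kind = rep("well", length(cen)), sd = rep(30, length(cen))),
    chrom = "chr1", chromLength = max(cen) + 100, params = list(),
    seed = NA_real_)
  mkCalls <- function(cen) {
    if (length(cen) == 0L) return(nucleoscape:::.makeMap(NULL, 146))
    nucleoscape:::.makeMap(
      data.frame(chrom = "chr1", center = cen, alpha = 0.2, height = 1,
                 s = 10, support = 1L), 146)
  }
  # perfect calls: all distances zero
  pe <- positioningError(mkTruth(c(300, 600)), mkCalls(c(300, 600)))
  expect_equal(pe$distances, c(0, 0))
  # single call 10 bp off
  pe2 <- positioningError(mkTruth(300), mkCalls(310))
  expect_equal(pe2$distances, 10)
  # unmatched items are counted, not matched beyond the cap
  pe3 <- positioningError(mkTruth(c(300, 2000)), mkCalls(300))
  expect_equal(pe3$nMatched, 1L)
  expect_equal(pe3$unmatchedTruth, 1L)
  # empty calls
  pe4 <- positioningError(mkTruth(300), mkCalls(numeric()))
  expect_equal(pe4$nMatched, 0L)
  expect_equal(pe4$unmatchedTruth, 1L)
})

test_that("greedy matching agrees with exhaustive assignment when truths are separated", {
  # independent oracle: minimise total distance over all assignments
  oracleMatch <- function(calls, truth, cap = 100) {
    best <- NULL; bestCost <- Inf
    k <- min(length(calls), length(truth))
    for (sz in k:0) {
      callSets <- combn(seq_along(calls), sz, simplify = FALSE)
      truthPerms <- if (sz > 0)
        combn(seq_along(truth), sz, simplify = FALSE) else list(integer())
      for (cs in callSets) for (ts in truthPerms) {
        for (perm in if (sz > 1) .permute(ts) else list(ts)) {
          dd <- abs(calls[cs] - truth[perm])
          if (all(dd <= cap) && sum(dd) < bestCost) {
            bestCost <- sum(dd); best <- sort(dd)
          }
        }
      }
      if (!is.null(best)) return(best)  # maximum matching size first
    }
    numeric()
  }
  .permute <- function(x) {
    if (length(x) <= 1) return(list(x))
    do.call(c, lapply(seq_along(x), function(i)
      lapply(.permute(x[-i]), function(p) c(x[i], p))))
  }
  set.seed(19)
  for (rep in 1:10) {
    nT <- sample(2:5, 1)
    truth <- sort(runif(nT, 0, 3000))
    truth <- truth[c(TRUE, diff(truth) > 250)]     # well separated
    calls <- truth + runif(length(truth), -40, 40)
    calls <- sample(calls)                          # shuffle
    mkT <- new("SyntheticMap", nucleosomes = S4Vectors::DataFrame(
      center = truth, kind = rep("well", length(truth)),
      sd = rep(30, length(truth))), chrom = "chr1",
      chromLength = 4000, params = list(), seed = NA_real_)
    mkC <- nucleoscape:::.makeMap(data.frame(chrom = "chr1", center = calls,
      alpha = 0.2, height = 1, s = 10, support = 1L), 146)
    pe <- positioningError(mkT, mkC)
    expect_equal(sort(pe$distances), oracleMatch(sort(calls), truth),
                 tolerance = 1e-9)
  }
})

test_that("adjacent distances are histogrammed in aligned bins", {
  mkCalls <- function(cen) nucleoscape:::.makeMap(
    data.frame(chrom = "chr1", center = cen, alpha = 0.2, height = 1,
               s = 10, support = 1L), 146)
  h <- adjacentDistanceDistribution(mkCalls(c(100, 267, 434)), binWidth = 5)
  expect_equal(h$binCenter[h$count > 0], 167.5)
  expect_equal(sum(h$count), 2L)
  # fewer than two calls: empty histogram
  expect_equal(nrow(adjacentDistanceDistribution(mkCalls(100), 5)), 0L)
  # maps respect the non-overlap floor, so no mass below 146
  bench <- benchmarkDataset()
  hb <- adjacentDistanceDistribution(bench$calls, 5)
  expect_true(all(hb$binStart[hb$count > 0] >= 145))
})

test_that("chain filtering merges tightly spaced calls into single counts", {
  mkCalls <- function(cen) {
    if (length(cen) == 0L) return(nucleoscape:::.makeMap(NULL, 146))
    nucleoscape:::.makeMap(
      data.frame(chrom = "chr1", center = cen, alpha = 0.2, height = 1,
                 s = 10, support = 1L), 146)
  }
  expect_equal(filterCloseNucleosomes(mkCalls(c(100, 247, 500)), 148), 2L)
  expect_equal(filterCloseNucleosomes(mkCalls(c(100, 300, 500)), 148), 3L)
  expect_equal(filterCloseNucleosomes(mkCalls(c(100, 247, 394)), 148), 1L)
  expect_equal(filterCloseNucleosomes(mkCalls(numeric()), 148), 0L)
})

test_that("subsampling is uniform, seed-stable and size-exact", {
  fr <- fragmentsAt(seq(200, 200 + 99 * 200, by = 200))
  expect_identical(subsampleFragments(fr, 1.0), fr)
  s1 <- subsampleFragments(fr, 0.5, seed = 6)
  expect_length(s1, 50L)
  expect_identical(as.data.frame(s1),
                   as.data.frame(subsampleFragments(fr, 0.5, seed = 6)))
  expect_true(all(as.data.frame(s1)$start %in% as.data.frame(fr)$start))
  expect_error(subsampleFragments(fr, 0), "fraction")
})

test_that("the pipeline recovers a fuzzy-free map with high sensitivity", {
  bench <- benchmarkDataset()
  pe <- positioningError(bench$sim$map, bench$calls, maxDist = 100)
  within40 <- sum(pe$distances <= 40)
  expect_gte(within40 / nNucleosomes(bench$sim$map), 0.9)
})
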