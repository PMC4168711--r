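#' @include AllClasses.R AllGenerics.R consensus.R
#' @importFrom stats rnorm runif sd
#' @importFrom withr with_seed
NULL

.withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Simulate reads for a single (possibly fuzzy) nucleosome
#'
#' Generates fixed-length fragments whose midpoints are i.i.d. Gaussian
#' around one nucleosome center — the minimal low-coverage scenario: by
#' default 20 fragments of 146 bp around a dyad at 300 bp with midpoint
#' standard deviation 40 (about 20-fold coverage).
#'
#' @param center dyad position in bp.
#' @param sd midpoint standard deviation in bp.
#' @param nReads number of fragments.
#' @param readLen fragment length in bp.
#' @param seed optional integer seed for reproducibility.
#' @param chrom chromosome name for the output ranges.
#' @return a [GenomicRanges::GRanges] of fragments.
#' @examples
#' fr <- simulateToy(seed = 1)
#' length(fr); GenomicRanges::width(fr)[1]
#' @export
simulateToy <- function(center = 300, sd = 40, nReads = 20, readLen = 146,
                        seed = NULL, chrom = "synthChr") {
  stopifnot(nReads >= 1, readLen > 0, sd >= 0)
  mids <- .withSeed(seed, round(rnorm(nReads, center, sd)))
  start0 <- mids - readLen %/% 2
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1, width = readLen))
}

#' Generate a synthetic nucleosome map with reads
#'
#' Emulates the standard synthetic benchmark for nucleosome callers:
#' \code{wpNum} well-positioned nucleosomes on a regular grid with spacing
#' \code{nucLen + linLen} (147 + 20 bp by default, a ~167 bp periodicity), of
#' which \code{wpDel} are deleted uniformly at random; \code{fuzNum} fuzzy
#' nucleosomes at uniform random positions, which may overlap anything.
#' For each surviving nucleosome, fragments of length \code{nucLen} are
#' sampled with midpoints Gaussian around its center (sd \code{wpVar} for
#' well-positioned, \code{fuzVar} for fuzzy); the per-nucleosome fragment
#' count is drawn uniformly between \code{maxCover/2} and \code{maxCover},
#' so \code{maxCover} bounds the per-nucleosome coverage (overlapping fuzzy
#' nucleosomes can still stack locally).
#'
#' @param wpNum number of grid positions for well-positioned nucleosomes.
#' @param wpDel number of grid positions deleted at random (\code{<= wpNum}).
#' @param wpVar midpoint sd for well-positioned nucleosomes (bp).
#' @param fuzNum number of fuzzy nucleosomes.
#' @param fuzVar midpoint sd for fuzzy nucleosomes (bp).
#' @param maxCover upper bound on per-nucleosome fold coverage.
#' @param nucLen nucleosome core length (bp), also the fragment length.
#' @param linLen linker length between grid positions (bp).
#' @param seed optional integer seed.
#' @param chrom chromosome name.
#' @param reads generate fragments (set FALSE for the truth map alone).
#' @return list with \code{map} (a [SyntheticMap-class]) and
#'   \code{fragments} (a [GenomicRanges::GRanges], or NULL when
#'   \code{reads = FALSE}).
#' @examples
#' sim <- syntheticNucleosomeMap(wpNum = 20, wpDel = 2, seed = 1)
#' nNucleosomes(sim$map)
#' @export
syntheticNucleosomeMap <- function(wpNum = 1100, wpDel = 100, wpVar = 30,
                                   fuzNum = 0, fuzVar = 50, maxCover = 70,
                                   nucLen = 147, linLen = 20, seed = NULL,
                                   chrom = "synthChr", reads = TRUE) {
  if (wpDel > wpNum) stop("wpDel must not exceed wpNum")
  stopifnot(wpNum >= 0, fuzNum >= 0, maxCover >= 1, nucLen > 0, linLen >= 0)
  spacing <- nucLen + linLen
  chromLength <- wpNum * spacing + linLen
  .withSeed(seed, {
    gridCenters <- linLen + (seq_len(wpNum) - 1) * spacing + nucLen / 2
    keep <- if (wpDel > 0) {
      del <- sample.int(wpNum, wpDel)
      gridCenters[-del]
    } else gridCenters
    fuzCenters <- if (fuzNum > 0)
      runif(fuzNum, nucLen / 2, chromLength - nucLen / 2) else numeric()
    df <- S4Vectors::DataFrame(
      center = c(keep, fuzCenters),
      kind = c(rep("well", length(keep)), rep("fuzzy", length(fuzCenters))),
      sd = c(rep(wpVar, length(keep)), rep(fuzVar, length(fuzCenters))))
    df <- df[order(df$center), , drop = FALSE]
    map <- new("SyntheticMap", nucleosomes = df, chrom = chrom,
               chromLength = chromLength,
               params = list(wpNum = wpNum, wpDel = wpDel, wpVar = wpVar,
                             fuzNum = fuzNum, fuzVar = fuzVar,
                             maxCover = maxCover, nucLen = nucLen,
                             linLen = linLen),
               seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
    fragments <- NULL
    if (reads && nrow(df) > 0L) {
      counts <- sample(seq.int(ceiling(maxCover / 2), maxCover),
                       nrow(df), replace = TRUE)
      centers <- rep(df$center, counts)
      sds <- rep(df$sd, counts)
      mids <- rnorm(length(centers), centers, sds)
      start0 <- round(mids - nucLen / 2)
      ok <- start0 >= 0 & start0 + nucLen <= chromLength
      fragments <- sort(GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0[ok] + 1, width = nucLen)))
    } else if (reads) {
      fragments <- GenomicRanges::GRanges()
    }
    list(map = map, fragments = fragments)
  })
}

#' Positioning error of a call set against a synthetic truth
#'
#' Matches each call to the nearest true nucleosome by greedy nearest-pair
#' assignment (smallest center distance first, each truth and each call used
#' at most once, matches capped at \code{maxDist}) and returns the matched
#' distance distribution plus the counts of unmatched calls and truths.
#'
#' @param trueMap a [SyntheticMap-class].
#' @param called a [NucleosomeMap-class].
#' @param maxDist cap on the match distance in bp.
#' @return list with \code{distances} (bp, one per matched pair),
#'   \code{nMatched}, \code{unmatchedCalls}, \code{unmatchedTruth}.
#' @export
positioningError <- function(trueMap, called, maxDist = 100) {
  truth <- trueCenters(trueMap)
  calls <- callCenters(called)
  if (length(calls) == 0L || length(truth) == 0L)
    return(list(distances = numeric(), nMatched = 0L,
                unmatchedCalls = length(calls),
                unmatchedTruth = length(truth)))
  d <- abs(outer(calls, truth, "-"))
  cand <- which(d <= maxDist, arr.ind = TRUE)
  if (nrow(cand)) cand <- cand[order(d[cand]), , drop = FALSE]
  usedCall <- logical(length(calls))
  usedTruth <- logical(length(truth))
  dist <- numeric()
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, 1]; ti <- cand[i, 2]
    if (!usedCall[ci] && !usedTruth[ti]) {
      usedCall[ci] <- TRUE
      usedTruth[ti] <- TRUE
      dist <- c(dist, d[ci, ti])
    }
  }
  list(distances = dist, nMatched = length(dist),
       unmatchedCalls = sum(!usedCall), unmatchedTruth = sum(!usedTruth))
}

#' Distribution of distances between adjacent calls
#'
#' Histograms the center-to-center distances of consecutive calls (per
#' chromosome) in fixed-width bins aligned at multiples of the bin width.
#' Well-positioned chromatin with 147 bp cores and 20 bp linkers shows a
#' mode at the bin containing 167 bp (and a harmonic at 334 bp where a
#' nucleosome was missed).
#'
#' @param map a [NucleosomeMap-class] (sorted by construction).
#' @param binWidth bin width in bp.
#' @return data.frame with \code{binStart}, \code{binCenter}, \code{count};
#'   zero rows when the map has fewer than two calls on every chromosome.
#' @export
adjacentDistanceDistribution <- function(map, binWidth = 5) {
  stopifnot(binWidth > 0)
  gr <- map@calls
  cen <- callCenters(map)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  dists <- unlist(lapply(split(cen, chrom), function(x)
    if (length(x) >= 2L) diff(sort(x)) else numeric()), use.names = FALSE)
  if (length(dists) == 0L)
    return(data.frame(binStart = numeric(), binCenter = numeric(),
                      count = integer()))
  bin <- floor(dists / binWidth)
  tab <- table(bin)
  binStart <- as.numeric(names(tab)) * binWidth
  data.frame(binStart = binStart, binCenter = binStart + binWidth / 2,
             count = as.integer(tab))
}

#' Count calls after merging tightly spaced neighbours
#'
#' Consecutive calls whose center gap is at most \code{threshold} bp are
#' chained together and every chain counts as one nucleosome — the cleaning
#' step that exposes over-reporting callers, which place many calls exactly
#' one footprint apart.
#'
#' @param map a [NucleosomeMap-class].
#' @param threshold chain gap in bp (default 148).
#' @return integer: the filtered nucleosome count.
#' @examples
#' # gaps 147 and 253: the first pair chains, count 2
#' @export
filterCloseNucleosomes <- function(map, threshold = 148) {
  cen <- callCenters(map)
  if (length(cen) == 0L) return(0L)
  chrom <- as.character(GenomicRanges::seqnames(map@calls))
  sum(vapply(split(cen, chrom), function(x) {
    x <- sort(x)
    if (length(x) == 1L) return(1L)
    sum(diff(x) > threshold) + 1L
  }, integer(1)))
}

#' Randomly subsample fragments
#'
#' Uniform subset without replacement of size \code{floor(fraction * n)},
#' reproducible per seed; fraction 1 returns the input unchanged.
#'
#' @param fragments a [GenomicRanges::GRanges].
#' @param fraction fraction in (0, 1].
#' @param seed optional integer seed.
#' @return a [GenomicRanges::GRanges], sorted.
#' @export
subsampleFragments <- function(fragments, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(fragments)
  k <- floor(fraction * n)
  if (k == n) return(fragments)
  idx <- .withSeed(seed, sort(sample.int(n, k)))
  fragments[idx]
}
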