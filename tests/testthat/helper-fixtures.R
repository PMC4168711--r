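suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# GRanges fragments from 0-based half-open coordinates
makeFragments <- function(start0, end0, chrom = "chr1") {
  GRanges(chrom, IRanges(start = start0 + 1, end = end0))
}

# fragments of fixed even length centred on given (integer) midpoints
fragmentsAt <- function(mids, len = 146, chrom = "chr1") {
  makeFragments(mids - len / 2, mids + len / 2, chrom)
}

# a small config so unit tests stay fast; defaults elsewhere
testConfig <- function(m = 10L, ...) ProfileConfig(m = m, ...)

# construct a PeakSet directly from centre positions (for consensus tests)
makePeakSet <- function(q, alpha, chrom = "chr1") {
  q <- sort(as.numeric(q))
  n <- length(q)
  pk <- S4Vectors::DataFrame(q = q, qRaw = q, s = rep(50, n),
                             height = rep(1, n),
                             basinLeft = q - 60, basinRight = q + 60,
                             support = rep(1L, n))
  new("PeakSet", chrom = chrom, alpha = alpha, peaks = pk)
}

# brute-force extrema oracle: windowed comparison on the raw curve, with the
# same plateau and endpoint conventions as the scanner but implemented
# independently (per-position neighbourhood search, not a run-length scan)
oracleExtrema <- function(values) {
  l <- length(values)
  if (l < 3L) return(list(maxima = integer(), minima = integer()))
  maxima <- integer(); minima <- integer()
  i <- 1L
  while (i <= l) {
    j <- i
    while (j < l && values[j + 1L] == values[i]) j <- j + 1L
    leftVal <- if (i > 1L) values[i - 1L] else NA
    rightVal <- if (j < l) values[j + 1L] else NA
    pos <- (i - 1L + j - 1L) %/% 2L  # floored plateau midpoint, 0-based
    if (!is.na(leftVal) && !is.na(rightVal)) {
      if (values[i] > leftVal && values[i] > rightVal)
        maxima <- c(maxima, pos)
      if (values[i] < leftVal && values[i] < rightVal)
        minima <- c(minima, pos)
    }
    i <- j + 1L
  }
  list(maxima = maxima, minima = sort(unique(c(0L, minima, l - 1L))))
}

# Write a paired-end SAM file; one row per fragment, 0-based start and insert
# size. Optional per-fragment mapq, plus unpaired/secondary extras.
writeTestSam <- function(path, chrom = "chr1", chromLen = 100000L,
                         start0, insert, mapq = NULL, readLen = 20L,
                         extraLines = character()) {
  n <- length(start0)
  if (is.null(mapq)) mapq <- rep(60L, n)
  stopifnot(length(insert) == n, all(insert >= readLen))
  pos1 <- start0 + 1L
  pos2 <- start0 + insert - readLen + 1L
  seqs <- strrep("A", readLen)
  qual <- strrep("I", readLen)
  recs <- character(0)
  for (i in seq_len(n)) {
    nm <- sprintf("frag%03d", i)
    recs <- c(recs,
      sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
              nm, chrom, pos1[i], mapq[i], readLen, pos2[i], insert[i],
              seqs, qual),
      sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
              nm, chrom, pos2[i], mapq[i], readLen, pos1[i], -insert[i],
              seqs, qual))
  }
  recs <- c(recs, extraLines)
  # coordinate sort by POS
  pos <- as.integer(vapply(strsplit(recs, "\t"), `[`, character(1), 4L))
  recs <- recs[order(pos)]
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromLen), recs), path)
  path
}

# shared, lazily built 1/10-scale fuzzy-free benchmark (seed fixed so every
# block sees the same dataset)
.benchCache <- new.env(parent = emptyenv())
benchmarkDataset <- function() {
  if (is.null(.benchCache$sim)) {
    .benchCache$sim <- syntheticNucleosomeMap(wpNum = 110, wpDel = 10,
                                              fuzNum = 0, seed = 1)
    .benchCache$calls <- suppressWarnings(
      callNucleosomes(.benchCache$sim$fragments))
  }
  list(sim = .benchCache$sim, calls = .benchCache$calls)
}
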