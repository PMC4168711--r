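#' @include AllClasses.R AllGenerics.R peaks.R
NULL

#' Do two calls overlap?
#'
#' Two nucleosome candidates overlap when their centers are closer than the
#' nucleosome footprint: |q1 - q2| < nucSize (strict, so centers exactly
#' nucSize apart do not overlap).
#'
#' @param q1,q2 center positions in bp (vectorised).
#' @param nucSize footprint in bp (default 146).
#' @return logical.
#' @examples
#' peaksOverlap(300, 445) # TRUE  (distance 145)
#' peaksOverlap(300, 446) # FALSE (distance 146)
#' @export
peaksOverlap <- function(q1, q2, nucSize = 146) {
  abs(q1 - q2) < nucSize
}

# Assemble a NucleosomeMap from a data.frame of admitted calls.
.makeMap <- function(df, nucSize, params = list(), stats = list()) {
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(center = numeric(),
      alpha = numeric(), height = numeric(), s = numeric(),
      support = integer())
    return(new("NucleosomeMap", calls = gr, nucSize = nucSize,
               params = params, stats = stats))
  }
  ord <- order(df$chrom, df$center)
  df <- df[ord, , drop = FALSE]
  cen <- round(df$center)
  gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = cen - 73 + 1, end = cen + 74))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(center = df$center,
    alpha = df$alpha, height = df$height, s = df$s,
    support = as.integer(df$support))
  new("NucleosomeMap", calls = gr, nucSize = nucSize, params = params,
      stats = stats)
}

# Internal: shared admission bookkeeping on one chromosome's peak sets.
# Returns a data.frame of admitted calls plus per-scale counters.
.greedyAdmit <- function(peakSets, nucSize) {
  alphas <- vapply(peakSets, scaleFactor, numeric(1))
  if (length(alphas) > 1L && any(diff(alphas) <= 0))
    stop("peak sets must be ordered by strictly increasing alpha")
  chroms <- unique(vapply(peakSets, function(ps) ps@chrom, character(1)))
  if (length(chroms) > 1L)
    stop("peak sets span multiple chromosomes; build per chromosome")
  cCenters <- numeric()
  rows <- vector("list", length(peakSets))
  candPerScale <- integer(length(peakSets))
  admitPerScale <- integer(length(peakSets))
  for (k in seq_along(peakSets)) {
    pk <- peakSets[[k]]@peaks
    candPerScale[k] <- nrow(pk)
    if (nrow(pk) == 0L) next
    q <- pk$q                              # sorted by construction
    # a peak failing the within-set test (closer than nucSize to ANY other
    # peak of its own set) is dropped for this scale only; in sorted order
    # the nearest neighbours decide
    if (length(q) > 1L) {
      gapL <- c(Inf, diff(q))
      gapR <- c(diff(q), Inf)
      solo <- gapL >= nucSize & gapR >= nucSize
    } else solo <- TRUE
    idx <- which(solo)
    for (j in idx) {                       # left-to-right
      if (length(cCenters) == 0L ||
          all(abs(cCenters - q[j]) >= nucSize)) {
        cCenters <- c(cCenters, q[j])
        rows[[k]] <- rbind(rows[[k]], data.frame(
          chrom = peakSets[[k]]@chrom, center = q[j],
          alpha = peakSets[[k]]@alpha, height = pk$height[j], s = pk$s[j],
          support = pk$support[j]))
        admitPerScale[k] <- admitPerScale[k] + 1L
      }
    }
  }
  list(calls = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       candidates = candPerScale, admissions = admitPerScale,
       alphas = alphas)
}

#' Build the consensus nucleosome map from per-scale peak sets
#'
#' Processes peak sets from the finest to the coarsest scale. A peak is
#' admitted to the consensus only if (i) it does not overlap any other peak
#' of its own set (mutual overlap disqualifies both for that scale; they stay
#' eligible at coarser scales) and (ii) it does not overlap any call already
#' admitted. Admitted calls are never removed, so strongly positioned
#' nucleosomes settled at fine scales and fuzzy ones are filled in later from
#' smoother landscapes.
#'
#' @param peakSets list of [PeakSet-class] ordered by strictly increasing
#'   alpha, all on one chromosome, with recentered peaks.
#' @param nucSize overlap threshold in bp.
#' @param params optional configuration snapshot stored in the result.
#' @return a [NucleosomeMap-class].
#' @export
buildConsensus <- function(peakSets, nucSize = 146, params = list()) {
  res <- .greedyAdmit(peakSets, nucSize)
  .makeMap(res$calls, nucSize, params = params,
           stats = list(candidatesPerScale = res$candidates,
                        admissionsPerScale = res$admissions,
                        alphas = res$alphas))
}

#' Reference consensus by exhaustive pair checking
#'
#' Replays the same admission rule with quadratic all-pairs scans instead of
#' the sorted neighbour sweep; intended as an independent oracle for testing
#' [buildConsensus()] on small instances.
#'
#' @inheritParams buildConsensus
#' @param maxPeaks guard on the total number of peaks (default 1000).
#' @return a [NucleosomeMap-class].
#' @export
bruteForceConsensus <- function(peakSets, nucSize = 146, maxPeaks = 1000L) {
  total <- sum(vapply(peakSets, function(ps) nrow(ps@peaks), integer(1)))
  if (total > maxPeaks)
    stop("too many peaks for the exhaustive oracle")
  alphas <- vapply(peakSets, scaleFactor, numeric(1))
  if (length(alphas) > 1L && any(diff(alphas) <= 0))
    stop("peak sets must be ordered by strictly increasing alpha")
  cRows <- NULL
  for (ps in peakSets) {
    pk <- ps@peaks
    if (nrow(pk) == 0L) next
    for (j in seq_len(nrow(pk))) {
      qj <- pk$q[j]
      clashSet <- FALSE
      for (j2 in seq_len(nrow(pk))) {
        if (j2 != j && abs(pk$q[j2] - qj) < nucSize) { clashSet <- TRUE; break }
      }
      if (clashSet) next
      clashC <- FALSE
      if (!is.null(cRows)) {
        for (i in seq_len(nrow(cRows))) {
          if (abs(cRows$center[i] - qj) < nucSize) { clashC <- TRUE; break }
        }
      }
      if (!clashC) {
        cRows <- rbind(cRows, data.frame(chrom = ps@chrom, center = qj,
          alpha = ps@alpha, height = pk$height[j], s = pk$s[j],
          support = pk$support[j]))
      }
    }
  }
  .makeMap(cRows, nucSize)
}

#' Call nucleosomes from paired-end fragments
#'
#' End-to-end pipeline: build the landscape family over each chromosome,
#' detect candidate peaks on every landscape, recenter them on fragment
#' midpoint centroids, and merge fine-to-coarse into the final
#' non-overlapping consensus map. Chromosomes are processed independently.
#'
#' @param fragments a [GenomicRanges::GRanges] of fragments, e.g. from
#'   [readFragments()] or [simulateToy()].
#' @param region optional GRanges of length 1 restricting the analysis (its
#'   chromosome only); by default the padded fragment span of each
#'   chromosome present.
#' @param config a [ProfileConfig-class].
#' @return a [NucleosomeMap-class].
#' @examples
#' fr <- simulateToy(seed = 7)
#' m <- callNucleosomes(fr, config = ProfileConfig(m = 12))
#' callCenters(m)
#' @export
callNucleosomes <- function(fragments, region = NULL,
                            config = ProfileConfig()) {
  nucSize <- config@nucSize
  params <- list(alphas = config@alphas, A = config@A,
                 epsilon = config@epsilon, nucSize = nucSize,
                 truncation = config@truncation)
  if (length(fragments) == 0L)
    return(.makeMap(NULL, nucSize, params = params))
  if (!is.null(region)) {
    keep <- as.character(GenomicRanges::seqnames(fragments)) ==
      as.character(GenomicRanges::seqnames(region))
    fragments <- fragments[keep]
    chroms <- as.character(GenomicRanges::seqnames(region))
  } else {
    chroms <- unique(as.character(GenomicRanges::seqnames(fragments)))
  }
  allRows <- NULL
  stats <- list(nFragments = length(fragments), perChrom = list())
  for (ch in chroms) {
    frs <- fragments[as.character(GenomicRanges::seqnames(fragments)) == ch]
    if (length(frs) == 0L) next
    reg <- if (!is.null(region)) region else NULL
    fam <- buildLandscapeFamily(frs, reg, config)
    peakSets <- lapply(fam$landscapes, function(ls)
      recenterPeaks(detectPeaks(ls), frs))
    res <- .greedyAdmit(peakSets, nucSize)
    allRows <- rbind(allRows, res$calls)
    stats$perChrom[[ch]] <- list(nFragments = length(frs),
      regionWidth = length(curveValues(fam$reference)),
      candidatesPerScale = res$candidates,
      admissionsPerScale = res$admissions)
  }
  .makeMap(allRows, nucSize, params = params, stats = stats)
}
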