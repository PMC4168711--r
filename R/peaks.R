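#' @include AllClasses.R AllGenerics.R profiles.R
NULL

#' Locate local extrema of a sampled curve
#'
#' One left-to-right scan over the run-length-compressed curve. Interior runs
#' strictly higher than both neighbours are maxima; runs strictly lower are
#' minima. A plateau contributes a single extremum at its floored midpoint.
#' Both region endpoints are always reported as minima, so that peak widths
#' and basins are well defined near the edges. Curves shorter than 3 samples
#' have no extrema.
#'
#' @param values numeric vector sampled at consecutive positions.
#' @return list with integer vectors \code{maxima} and \code{minima} of
#'   0-based positions, each sorted.
#' @examples
#' findExtrema(c(0, 1, 0))       # maxima 1; minima 0, 2
#' findExtrema(c(0, 1, 1, 0))    # plateau maximum at 1
#' @export
findExtrema <- function(values) {
  l <- length(values)
  if (l < 3L) return(list(maxima = integer(), minima = integer()))
  r <- rle(values)
  k <- length(r$values)
  ends <- cumsum(r$lengths)            # 1-based run ends
  starts <- ends - r$lengths + 1L
  mid0 <- (starts + ends) %/% 2L - 1L  # floored run midpoint, 0-based
  maxima <- integer()
  minima <- integer()
  if (k >= 3L) {
    i <- 2:(k - 1L)
    v <- r$values
    isMax <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
    isMin <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
    maxima <- mid0[i][isMax]
    minima <- mid0[i][isMin]
  }
  minima <- sort(unique(c(0L, minima, l - 1L)))
  list(maxima = maxima, minima = minima)
}

#' Detect candidate nucleosome peaks on a landscape
#'
#' A candidate is a pair (q, s): q a local maximum of the landscape and s the
#' distance to the nearest local minimum (region boundaries count as minima).
#' Each peak also records its basin, the interval between the two flanking
#' minima, which later defines which fragments belong to it.
#'
#' The landscape is a log enrichment ratio against the low-resolution
#' background, so only maxima with positive height mark candidate
#' nucleosomes: in zero-coverage gaps the log-ratio mirrors the background
#' profile and produces negative-height maxima that carry no reads. The
#' default \code{minHeight = 0} discards those; set it to \code{-Inf} to keep
#' every raw maximum.
#'
#' @param landscape a [Landscape-class].
#' @param minHeight candidates must exceed this landscape value.
#' @return a [PeakSet-class] sorted by position.
#' @export
detectPeaks <- function(landscape, minHeight = 0) {
  ext <- findExtrema(landscape@values)
  ext$maxima <- ext$maxima[landscape@values[ext$maxima + 1L] > minHeight]
  off <- landscape@offset
  empty <- S4Vectors::DataFrame(q = numeric(), qRaw = numeric(),
                                s = numeric(), height = numeric(),
                                basinLeft = numeric(), basinRight = numeric(),
                                support = integer())
  if (length(ext$maxima) == 0L)
    return(new("PeakSet", chrom = landscape@chrom, alpha = landscape@alpha,
               peaks = empty))
  qRaw <- off + ext$maxima
  minima <- off + ext$minima
  # flanking minima: every maximum lies strictly between two minima
  iLeft <- findInterval(qRaw, minima)
  basinLeft <- minima[iLeft]
  basinRight <- minima[pmin(iLeft + 1L, length(minima))]
  s <- pmin(qRaw - basinLeft, basinRight - qRaw)
  height <- landscape@values[ext$maxima + 1L]
  pk <- S4Vectors::DataFrame(q = as.numeric(qRaw), qRaw = as.numeric(qRaw),
                             s = as.numeric(s), height = height,
                             basinLeft = as.numeric(basinLeft),
                             basinRight = as.numeric(basinRight),
                             support = 0L)
  new("PeakSet", chrom = landscape@chrom, alpha = landscape@alpha, peaks = pk)
}

#' Recenter candidate peaks on their fragment-midpoint centroids
#'
#' Landscape peaks need not be symmetric, so each candidate's position is
#' replaced by the unweighted mean midpoint of the fragments assigned to it.
#' A fragment belongs to the peak whose basin contains its midpoint
#' (half-open on the right, so each midpoint is assigned to at most one peak
#' per scale). Peaks with no assigned fragments keep their raw position.
#'
#' @param peakSet a [PeakSet-class] from [detectPeaks()].
#' @param fragments the fragments of the processed region.
#' @return the [PeakSet-class] with updated \code{q} and \code{support}.
#' @export
recenterPeaks <- function(peakSet, fragments) {
  pk <- peakSet@peaks
  if (nrow(pk) == 0L || length(fragments) == 0L) return(peakSet)
  mu <- fragmentMidpoints(fragments)
  # basins are consecutive inter-minima intervals, so assignment reduces to a
  # shared findInterval over the basin boundaries (right-open, unique)
  bnd <- sort(unique(c(pk$basinLeft, pk$basinRight)))
  muIdx <- findInterval(mu, bnd)
  pkIdx <- findInterval(pk$qRaw, bnd)
  cnt <- tabulate(muIdx, nbins = length(bnd))
  sums <- numeric(length(bnd))
  keep <- muIdx >= 1L
  if (any(keep)) {
    agg <- rowsum(mu[keep], muIdx[keep])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  n <- cnt[pkIdx]
  has <- n > 0L
  pk$q[has] <- sums[pkIdx[has]] / n[has]
  pk$support <- as.integer(n)
  if (any(!has))
    warning(sprintf("%d peak(s) at alpha %.3g had no assigned fragments",
                    sum(!has), peakSet@alpha))
  ord <- order(pk$q)
  peakSet@peaks <- pk[ord, , drop = FALSE]
  peakSet
}
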