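#' @include AllClasses.R AllGenerics.R
#' @useDynLib nucleoscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm
NULL

# Kernel table shared across scales and fragments of the same length; keyed by
# (alpha, rounded length, truncation, sub-bp phase of the midpoint).
.kernelCache <- new.env(parent = emptyenv())

.kernelKey <- function(alpha, w, truncation, frac)
  sprintf("%.12g|%d|%g|%g", alpha, w, truncation, frac)

#' Tabulate the truncated Gaussian read kernel
#'
#' Each fragment of length \code{w} contributes a Gaussian with standard
#' deviation \eqn{\sigma = \alpha w} centred on its midpoint. The kernel is
#' tabulated once per (alpha, rounded length) pair at integer offsets within
#' \code{truncation} sigma of the centre and reused across fragments; because
#' midpoints of odd-length fragments sit on half-integers, an optional
#' sub-base phase \code{frac} shifts the evaluation points accordingly.
#'
#' @param alpha scale factor (> 0).
#' @param w fragment length in bp (> 0); rounded to integer for table keying.
#' @param truncation support cutoff in multiples of sigma.
#' @param frac sub-base phase of the midpoint (0 or 0.5).
#' @return list with \code{offsets} (integer offsets from the midpoint's
#'   enclosing base), \code{values} (Gaussian density at \code{offsets - frac}),
#'   \code{radius} and \code{sigma}.
#' @examples
#' k <- readKernel(0.2, 146)
#' k$values[k$offsets == 0] # the mode, 1 / (alpha * w * sqrt(2*pi))
#' @export
readKernel <- function(alpha, w, truncation = 6, frac = 0) {
  stopifnot(alpha > 0, w > 0, truncation > 0, frac %in% c(0, 0.5))
  w <- as.integer(round(w))
  key <- .kernelKey(alpha, w, truncation, frac)
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  sigma <- alpha * w
  radius <- as.integer(ceiling(truncation * sigma + frac))
  offsets <- seq.int(-radius, radius)
  values <- dnorm(offsets - frac, mean = 0, sd = sigma)
  out <- list(offsets = offsets, values = values, radius = radius,
              sigma = sigma)
  assign(key, out, envir = .kernelCache)
  out
}

#' Per-fragment profile weights
#'
#' Fragment i receives weight \eqn{\beta_i = \gamma(w_i)/n}: uniform 1/n
#' damped for fragments shorter than the nucleosome footprint, so that short
#' (tall, narrow) Gaussians do not dominate the profile.
#'
#' @param w numeric vector of fragment lengths (bp).
#' @param n total number of fragments in the processed set.
#' @param config a [ProfileConfig-class].
#' @return numeric vector of weights, each at most 1/n.
#' @examples
#' fragmentWeights(c(146, 200, 73), n = 10)
#' @export
fragmentWeights <- function(w, n, config = ProfileConfig()) {
  if (n < 1) stop("empty fragment set")
  stopifnot(all(w > 0))
  config@gammaFun(w) / n
}

# Midpoints (0-based, fractional) of fragments stored as 1-based GRanges.
fragmentMidpoints <- function(fragments) {
  GenomicRanges::start(fragments) - 1 + GenomicRanges::width(fragments) / 2
}

# Normalise a region argument to list(chrom, start0, l). A GRanges of length 1
# is accepted; NULL derives the padded span of the fragments.
.resolveRegion <- function(region, fragments = NULL, pad = 0) {
  if (is.null(region)) {
    if (is.null(fragments) || length(fragments) == 0L)
      stop("cannot derive a region from an empty fragment set")
    ch <- unique(as.character(GenomicRanges::seqnames(fragments)))
    if (length(ch) != 1L)
      stop("fragments span multiple chromosomes; supply an explicit region")
    s0 <- max(0, min(GenomicRanges::start(fragments)) - 1 - pad)
    e0 <- max(GenomicRanges::end(fragments)) + pad
    return(list(chrom = ch, start0 = s0, l = as.integer(e0 - s0)))
  }
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    return(list(chrom = as.character(GenomicRanges::seqnames(region)),
                start0 = GenomicRanges::start(region) - 1,
                l = GenomicRanges::width(region)))
  }
  stop("region must be NULL or a GRanges of length 1")
}

#' Compute the smoothed nucleosome profile at one scale
#'
#' Sums the weighted, truncated Gaussian kernels of all fragments over the
#' integer base positions of \code{region}. Fragments whose kernel support
#' misses the region contribute nothing; an empty fragment set yields an
#' all-zero profile (with a warning).
#'
#' @param fragments a [GenomicRanges::GRanges] of fragments (one range per
#'   paired-end template).
#' @param alpha scale factor.
#' @param region a GRanges of length 1, or NULL to use the padded fragment span.
#' @param config a [ProfileConfig-class].
#' @param weights optional precomputed per-fragment weights (defaults to
#'   [fragmentWeights()] over the supplied fragments).
#' @return a [ScaleProfile-class].
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 246))
#' p <- computeProfile(fr, alpha = 0.2,
#'                     region = GenomicRanges::GRanges("chr1",
#'                              IRanges::IRanges(1, 400)))
#' which.max(curveValues(p)) + curveStart(p) - 1 # the fragment midpoint
#' @export
computeProfile <- function(fragments, alpha, region = NULL,
                           config = ProfileConfig(), weights = NULL) {
  stopifnot(alpha > 0)
  reg <- .resolveRegion(region, fragments, pad = config@nucSize)
  if (length(fragments) == 0L) {
    warning("empty fragment set: returning an all-zero profile")
    return(new("ScaleProfile", chrom = reg$chrom, offset = reg$start0,
               values = numeric(reg$l), alpha = alpha))
  }
  onChrom <- as.character(GenomicRanges::seqnames(fragments)) == reg$chrom
  if (!all(onChrom)) stop("all fragments must lie on the region's chromosome")
  if (is.null(weights))
    weights <- fragmentWeights(GenomicRanges::width(fragments),
                               length(fragments), config)
  mu <- fragmentMidpoints(fragments)
  wlen <- as.integer(round(GenomicRanges::width(fragments)))
  frac <- mu - floor(mu)               # 0 for even lengths, 0.5 for odd
  p <- as.integer(floor(mu) - reg$start0)
  values <- numeric(reg$l)
  for (grp in split(seq_along(mu), paste(wlen, frac))) {
    kern <- readKernel(alpha, wlen[grp[1]], config@truncation, frac[grp[1]])
    values <- values + .accumulateKernel(reg$l, p[grp], weights[grp],
                                         kern$values, kern$radius)
  }
  new("ScaleProfile", chrom = reg$chrom, offset = reg$start0,
      values = values, alpha = alpha)
}

#' Compute the nucleosome landscape from a profile and its reference
#'
#' Pointwise log-ratio \eqn{N(x) = \log\{(S_\alpha(x)+\epsilon) /
#' (S_A(x)+\epsilon)\}}. Wherever the two profiles agree (including shared
#' zeros) the landscape is exactly 0.
#'
#' @param profile a [ScaleProfile-class] at the scale of interest.
#' @param reference the low-resolution reference [ScaleProfile-class].
#' @param epsilon positive pseudocount.
#' @return a [Landscape-class] at the profile's scale.
#' @export
computeLandscape <- function(profile, reference, epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  if (profile@chrom != reference@chrom ||
      profile@offset != reference@offset ||
      length(profile@values) != length(reference@values))
    stop("profile and reference cover different regions")
  vals <- log((profile@values + epsilon) / (reference@values + epsilon))
  new("Landscape", chrom = profile@chrom, offset = profile@offset,
      values = vals, alpha = profile@alpha)
}

#' Build the full landscape family over a region
#'
#' Computes the reference profile at scale \code{A} once, then one profile and
#' landscape per entry of the scale grid, all normalised by the same
#' reference. Kernel tables are shared across scales and fragments.
#'
#' @inheritParams computeProfile
#' @param keepProfiles logical; also return the per-scale profiles.
#' @return list with \code{landscapes} (list of [Landscape-class], increasing
#'   alpha), \code{reference} (the [ScaleProfile-class] at scale A) and, if
#'   requested, \code{profiles}.
#' @export
buildLandscapeFamily <- function(fragments, region = NULL,
                                 config = ProfileConfig(), weights = NULL,
                                 keepProfiles = FALSE) {
  reg <- .resolveRegion(region, fragments, pad = config@nucSize)
  regGR <- GenomicRanges::GRanges(reg$chrom,
           IRanges::IRanges(reg$start0 + 1, width = reg$l))
  if (is.null(weights) && length(fragments) > 0L)
    weights <- fragmentWeights(GenomicRanges::width(fragments),
                               length(fragments), config)
  reference <- computeProfile(fragments, config@A, regGR, config, weights)
  profiles <- lapply(config@alphas, function(a)
    computeProfile(fragments, a, regGR, config, weights))
  landscapes <- lapply(profiles, computeLandscape, reference = reference,
                       epsilon = config@epsilon)
  out <- list(landscapes = landscapes, reference = reference)
  if (keepProfiles) out$profiles <- profiles
  out
}

#' Export a profile or landscape as a wiggle/bedGraph track
#'
#' Writes the sampled per-base curve for inspection in a genome browser.
#'
#' @param curve a [ScaleProfile-class] or [Landscape-class].
#' @param path output file; the extension selects the format unless
#'   \code{format} is given.
#' @param format "wig" or "bedGraph".
#' @return the path, invisibly.
#' @export
exportCurve <- function(curve, path, format = c("wig", "bedGraph")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(curve@chrom,
        IRanges::IRanges(curve@offset + seq_along(curve@values), width = 1),
        score = curve@values)
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}
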