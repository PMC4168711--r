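#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Configuration for multi-scale nucleosome profiling
#'
#' Holds every tunable constant of the profiling algorithm: the grid of
#' smoothing scale factors \eqn{\alpha_k}, the low-resolution reference scale
#' \eqn{A}, the log-ratio pseudocount \eqn{\epsilon}, the nucleosome footprint
#' used for overlap checks and fragment weighting, the insert-size filter
#' bounds, the kernel truncation radius, and the short-fragment penalty
#' \eqn{\gamma(w)}.
#'
#' @slot alphas numeric, strictly increasing scale factors, all > 0.
#' @slot A numeric(1), reference scale; must exceed \code{max(alphas)}.
#' @slot epsilon numeric(1), positive pseudocount for the log-ratio landscape.
#' @slot nucSize numeric(1), nucleosome footprint in bp (overlap threshold and
#'   reference length of the weighting penalty).
#' @slot minInsert,maxInsert numeric(1), inclusive insert-size filter bounds in bp.
#' @slot truncation numeric(1), kernel support cutoff in multiples of sigma.
#' @slot gammaFun function mapping fragment length (bp) to a weight factor in
#'   (0, 1]; must be 1 at and above \code{nucSize} and nondecreasing below it.
#'
#' @seealso [ProfileConfig()] for the user-facing constructor.
#' @exportClass ProfileConfig
setClass("ProfileConfig",
  representation(
    alphas = "numeric",
    A = "numeric",
    epsilon = "numeric",
    nucSize = "numeric",
    minInsert = "numeric",
    maxInsert = "numeric",
    truncation = "numeric",
    gammaFun = "function"
  )
)

setValidity("ProfileConfig", function(object) {
  msg <- character()
  a <- object@alphas
  if (length(a) < 1L || any(!is.finite(a)) || any(a <= 0))
    msg <- c(msg, "'alphas' must be finite and positive")
  if (length(a) > 1L && any(diff(a) <= 0))
    msg <- c(msg, "'alphas' must be strictly increasing")
  if (length(object@A) != 1L || object@A <= max(a))
    msg <- c(msg, "'A' must be a single value greater than max(alphas)")
  if (length(object@epsilon) != 1L || object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be a single positive value")
  if (object@nucSize <= 0)
    msg <- c(msg, "'nucSize' must be positive")
  if (object@minInsert >= object@maxInsert)
    msg <- c(msg, "'minInsert' must be smaller than 'maxInsert'")
  if (object@truncation <= 0)
    msg <- c(msg, "'truncation' must be positive")
  g <- object@gammaFun
  gw <- g(c(10, object@nucSize / 2, object@nucSize, object@nucSize + 100))
  if (any(!is.finite(gw)) || any(gw <= 0) || any(gw > 1))
    msg <- c(msg, "'gammaFun' must map lengths into (0, 1]")
  if (any(abs(gw[3:4] - 1) > 1e-12))
    msg <- c(msg, "'gammaFun' must equal 1 at and above nucSize")
  if (gw[1] > gw[2] + 1e-12)
    msg <- c(msg, "'gammaFun' must be nondecreasing below nucSize")
  if (length(msg)) msg else TRUE
})

#' Create a profiling configuration
#'
#' @param m integer, number of smoothing scales (profiles/landscapes) to build.
#' @param alphaRange numeric(2), inclusive range of the scale grid; the grid is
#'   \code{m} equally spaced values spanning it.
#' @param A reference (low-resolution) scale used for landscape normalisation.
#' @param epsilon pseudocount added to numerator and denominator of the
#'   landscape log-ratio.
#' @param nucSize nucleosome footprint in bp.
#' @param minInsert,maxInsert inclusive insert-size filter bounds in bp.
#' @param truncation kernel support cutoff in multiples of sigma.
#' @param gammaFun penalty function for short fragments; the default is a
#'   linear ramp \code{min(1, w / nucSize)}.
#'
#' @return A [ProfileConfig-class] object.
#' @examples
#' cfg <- ProfileConfig()
#' profileAlphas(cfg)[1:3]
#' @export
ProfileConfig <- function(m = 40L, alphaRange = c(0.05, 0.63), A = 1.5,
                          epsilon = 1e-6, nucSize = 146, minInsert = 40,
                          maxInsert = 1000, truncation = 6,
                          gammaFun = NULL) {
  stopifnot(length(alphaRange) == 2L, alphaRange[1] < alphaRange[2], m >= 1L)
  if (is.null(gammaFun)) {
    force(nucSize)
    gammaFun <- function(w) pmin(1, w / nucSize)
  }
  alphas <- if (m == 1L) alphaRange[1] else
    seq(alphaRange[1], alphaRange[2], length.out = m)
  new("ProfileConfig", alphas = alphas, A = A, epsilon = epsilon,
      nucSize = nucSize, minInsert = minInsert, maxInsert = maxInsert,
      truncation = truncation, gammaFun = gammaFun)
}

# Virtual parent of per-base genomic tracks sampled at consecutive integer
# positions; `offset` is the 0-based coordinate of values[1].
setClass("GenomicCurve",
  representation("VIRTUAL",
    chrom = "character",
    offset = "numeric",
    values = "numeric"
  )
)

setValidity("GenomicCurve", function(object) {
  if (length(object@chrom) != 1L) return("'chrom' must be a single name")
  if (length(object@offset) != 1L || object@offset != floor(object@offset))
    return("'offset' must be a single integer-valued coordinate")
  TRUE
})

#' Smoothed nucleosome profile at one scale
#'
#' The profile \eqn{S_\alpha(x) = \sum_i \beta_i f_i(x)} where each mapped
#' fragment contributes a Gaussian centred on its midpoint with standard
#' deviation \eqn{\alpha w_i}. Values are sampled at consecutive integer
#' base positions starting at the 0-based coordinate \code{curveStart(x)}.
#'
#' @slot chrom chromosome name.
#' @slot offset 0-based coordinate of the first sample.
#' @slot values nonnegative per-base profile values.
#' @slot alpha the scale factor used.
#' @exportClass ScaleProfile
setClass("ScaleProfile", contains = "GenomicCurve",
  representation(alpha = "numeric"))

setValidity("ScaleProfile", function(object) {
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0))
    return("profile values must be finite and nonnegative")
  TRUE
})

#' Nucleosome landscape at one scale
#'
#' The log-ratio \eqn{N_\alpha(x) = \log\{(S_\alpha(x)+\epsilon) /
#' (S_A(x)+\epsilon)\}} of a profile against the low-resolution reference,
#' sampled per base. Landscapes amplify candidate peaks in low-coverage
#' regions and damp them where coverage is high.
#'
#' @slot chrom chromosome name.
#' @slot offset 0-based coordinate of the first sample.
#' @slot values per-base log-ratio values (finite everywhere).
#' @slot alpha the scale factor of the numerator profile.
#' @exportClass Landscape
setClass("Landscape", contains = "GenomicCurve",
  representation(alpha = "numeric"))

setValidity("Landscape", function(object) {
  if (any(!is.finite(object@values)))
    return("landscape values must be finite")
  TRUE
})

#' Candidate nucleosome peaks detected on one landscape
#'
#' @slot chrom chromosome name.
#' @slot alpha scale of the landscape the peaks were detected on.
#' @slot peaks a [S4Vectors::DataFrame] with one row per candidate, sorted by
#'   center: \code{q} (center, fractional bp after recentering), \code{qRaw}
#'   (integer local-maximum position), \code{s} (distance to the nearest local
#'   minimum), \code{height} (landscape value at \code{qRaw}),
#'   \code{basinLeft}/\code{basinRight} (flanking minima bounding the peak's
#'   basin) and \code{support} (fragments assigned during recentering; 0 before).
#' @exportClass PeakSet
setClass("PeakSet",
  representation(chrom = "character", alpha = "numeric", peaks = "DataFrame"))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  need <- c("q", "qRaw", "s", "height", "basinLeft", "basinRight", "support")
  if (!all(need %in% colnames(p)))
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) > 1L && any(diff(p$q) < 0))
    return("peaks must be sorted by q")
  if (nrow(p) && any(p$s < 0))
    return("peak widths must be nonnegative")
  TRUE
})

#' Final consensus map of non-overlapping nucleosome calls
#'
#' The consensus set accumulated fine-to-coarse over the landscape family:
#' every pair of calls on the same chromosome is at least \code{nucSize} bp
#' apart (center-to-center). Calls carry provenance: the scale \code{alpha}
#' whose landscape produced them, the landscape height, the peak width
#' \code{s} and the number of supporting fragments.
#'
#' @slot calls a [GenomicRanges::GRanges] of 147 bp call footprints
#'   (center - 73 to center + 74, 0-based half-open), sorted, with metadata
#'   columns \code{center} (fractional bp), \code{alpha}, \code{height},
#'   \code{s}, \code{support}.
#' @slot nucSize numeric(1), the non-overlap threshold the map satisfies.
#' @slot params list, snapshot of the configuration used (may be empty).
#' @slot stats list of per-run counters (fragments, candidates per scale,
#'   admissions per scale) for instrumentation.
#' @exportClass NucleosomeMap
setClass("NucleosomeMap",
  representation(calls = "GRanges", nucSize = "numeric", params = "list",
                 stats = "list"))

setValidity("NucleosomeMap", function(object) {
  gr <- object@calls
  if (!"center" %in% colnames(S4Vectors::mcols(gr)))
    return("calls must carry a 'center' metadata column")
  cen <- S4Vectors::mcols(gr)$center
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    ci <- sort(cen[as.character(GenomicRanges::seqnames(gr)) == ch])
    if (length(ci) > 1L && any(diff(ci) < object@nucSize))
      return(sprintf("calls on %s violate the %g bp non-overlap rule",
                     ch, object@nucSize))
  }
  TRUE
})

#' Ground-truth synthetic nucleosome map
#'
#' Describes a simulated chromosome: well-positioned nucleosomes on a regular
#' grid with fixed linkers, plus fuzzy nucleosomes at uniform random
#' positions (which may overlap anything).
#'
#' @slot nucleosomes [S4Vectors::DataFrame] with columns \code{center} (bp),
#'   \code{kind} ("well" or "fuzzy") and \code{sd} (midpoint standard
#'   deviation used when sampling reads).
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot params list of generator parameters (wpNum, wpDel, wpVar, fuzNum,
#'   fuzVar, maxCover, nucLen, linLen).
#' @slot seed integer seed used, or NA.
#' @exportClass SyntheticMap
setClass("SyntheticMap",
  representation(nucleosomes = "DataFrame", chrom = "character",
                 chromLength = "numeric", params = "list", seed = "numeric"))

setValidity("SyntheticMap", function(object) {
  df <- object@nucleosomes
  if (!all(c("center", "kind", "sd") %in% colnames(df)))
    return("nucleosomes must have columns center, kind, sd")
  if (nrow(df) && any(df$sd <= 0))
    return("midpoint sd must be positive")
  if (nrow(df) && !all(df$kind %in% c("well", "fuzzy")))
    return("kind must be 'well' or 'fuzzy'")
  TRUE
})
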