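#' @include AllClasses.R
NULL

#' Accessors for nucleoscape objects
#'
#' Small accessor family: \code{profileAlphas} returns the scale grid of a
#' configuration, \code{scaleFactor} the scale of a profile, landscape or peak
#' set, \code{curveValues}/\code{curveStart}/\code{curveChrom} the sampled
#' track of a profile or landscape, \code{peaks} the candidate table of a
#' [PeakSet-class], \code{nucCalls} the call ranges of a
#' [NucleosomeMap-class], \code{callCenters} their (fractional) centers and
#' \code{trueCenters} the ground-truth centers of a [SyntheticMap-class].
#'
#' @param x the object.
#' @name accessors
#' @return the corresponding slot content; see Details.
NULL

#' @rdname accessors
#' @export
setGeneric("profileAlphas", function(x) standardGeneric("profileAlphas"))

#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))

#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname accessors
#' @export
setGeneric("curveStart", function(x) standardGeneric("curveStart"))

#' @rdname accessors
#' @export
setGeneric("curveChrom", function(x) standardGeneric("curveChrom"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("nucCalls", function(x) standardGeneric("nucCalls"))

#' @rdname accessors
#' @export
setGeneric("callCenters", function(x) standardGeneric("callCenters"))

#' @rdname accessors
#' @export
setGeneric("trueCenters", function(x) standardGeneric("trueCenters"))

#' @rdname accessors
setMethod("profileAlphas", "ProfileConfig", function(x) x@alphas)

#' @rdname accessors
setMethod("scaleFactor", "ScaleProfile", function(x) x@alpha)

#' @rdname accessors
setMethod("scaleFactor", "Landscape", function(x) x@alpha)

#' @rdname accessors
setMethod("scaleFactor", "PeakSet", function(x) x@alpha)

#' @rdname accessors
setMethod("curveValues", "GenomicCurve", function(x) x@values)

#' @rdname accessors
setMethod("curveStart", "GenomicCurve", function(x) x@offset)

#' @rdname accessors
setMethod("curveChrom", "GenomicCurve", function(x) x@chrom)

#' @rdname accessors
setMethod("peaks", "PeakSet", function(x) x@peaks)

#' @rdname accessors
setMethod("nucCalls", "NucleosomeMap", function(x) x@calls)

#' @rdname accessors
setMethod("callCenters", "NucleosomeMap",
          function(x) S4Vectors::mcols(x@calls)$center)

#' @rdname accessors
setMethod("trueCenters", "SyntheticMap", function(x) x@nucleosomes$center)

setMethod("show", "ProfileConfig", function(object) {
  a <- object@alphas
  cat("ProfileConfig:", length(a), "scales in [",
      format(min(a)), ",", format(max(a)), "], A =", object@A,
      "\n  epsilon =", format(object@epsilon),
      " nucSize =", object@nucSize,
      " insert filter [", object@minInsert, ",", object@maxInsert, "] bp",
      " truncation =", object@truncation, "sigma\n")
})

setMethod("show", "ScaleProfile", function(object) {
  cat(sprintf("ScaleProfile %s:%d-%d (alpha = %.4g, %d samples)\n",
              object@chrom, object@offset,
              object@offset + length(object@values), object@alpha,
              length(object@values)))
})

setMethod("show", "Landscape", function(object) {
  cat(sprintf("Landscape %s:%d-%d (alpha = %.4g, %d samples)\n",
              object@chrom, object@offset,
              object@offset + length(object@values), object@alpha,
              length(object@values)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet on %s at alpha = %.4g: %d candidate(s)\n",
              object@chrom, object@alpha, nrow(object@peaks)))
})

setMethod("show", "NucleosomeMap", function(object) {
  cat(sprintf("NucleosomeMap: %d non-overlapping call(s) (min spacing %g bp)\n",
              length(object@calls), object@nucSize))
  if (length(object@calls)) {
    alphas <- S4Vectors::mcols(object@calls)$alpha
    cat("  scales of origin:", paste(format(sort(unique(alphas)), digits = 3),
                                     collapse = " "), "\n")
  }
})

setMethod("show", "SyntheticMap", function(object) {
  df <- object@nucleosomes
  cat(sprintf(
    "SyntheticMap on %s (length %d bp): %d nucleosomes (%d well, %d fuzzy)\n",
    object@chrom, as.integer(object@chromLength), nrow(df),
    sum(df$kind == "well"), sum(df$kind == "fuzzy")))
})

#' Number of true nucleosomes or final calls
#'
#' @param x a [SyntheticMap-class] or [NucleosomeMap-class].
#' @return integer count.
#' @export
setGeneric("nNucleosomes", function(x) standardGeneric("nNucleosomes"))

#' @rdname nNucleosomes
setMethod("nNucleosomes", "SyntheticMap", function(x) nrow(x@nucleosomes))

#' @rdname nNucleosomes
setMethod("nNucleosomes", "NucleosomeMap", function(x) length(x@calls))
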