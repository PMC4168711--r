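#' @include AllClasses.R AllGenerics.R
#' @importFrom utils read.table write.table
NULL

# Apply the insert-size filter and report what was dropped.
.filterInserts <- function(gr, minInsert, maxInsert, verbose = TRUE) {
  w <- GenomicRanges::width(gr)
  keep <- w >= minInsert & w <= maxInsert
  if (verbose && any(!keep))
    message(sprintf("insert-size filter [%g, %g] bp removed %d of %d fragments",
                    minInsert, maxInsert, sum(!keep), length(gr)))
  gr[keep]
}

#' Read paired-end fragments from a BAM or SAM file
#'
#' Converts properly paired alignments into one fragment per template,
#' spanning the leftmost to the rightmost aligned base of the two mates.
#' Secondary, supplementary and unmapped records are skipped; with
#' \code{requireUnique}, records with mapping quality 0 (the multi-mapper
#' convention of common aligners) are skipped too. Fragments whose insert
#' size lies outside \code{[minInsert, maxInsert]} (inclusive) are then
#' removed, and filter counts are reported. Duplicate fragments are retained
#' (no deduplication).
#'
#' @param path a BAM file (coordinate-sorted; indexed if \code{region} is
#'   used) or a SAM file (converted on the fly).
#' @param region optional [GenomicRanges::GRanges] of length 1 restricting
#'   the query.
#' @param minInsert,maxInsert inclusive insert-size bounds in bp.
#' @param requireUnique drop mapping-quality-0 records.
#' @return a [GenomicRanges::GRanges] with one range per fragment (1-based
#'   start, so a fragment at 0-based 100-246 has start 101, end 246,
#'   width 146).
#' @export
readFragments <- function(path, region = NULL, minInsert = 40,
                          maxInsert = 1000, requireUnique = TRUE) {
  stopifnot(minInsert < maxInsert)
  if (!file.exists(path))
    stop("cannot read alignment file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("rname", "pos", "isize", "mapq")
  if (!is.null(region)) {
    ch <- as.character(GenomicRanges::seqnames(region))
    if (!ch %in% names(hdr))
      stop(sprintf("chromosome '%s' not in alignment header; available: %s",
                   ch, paste(names(hdr), collapse = ", ")))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = region)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  }
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  # keep the leftmost mate of each template (positive template length),
  # so every fragment is counted exactly once
  keep <- !is.na(res$isize) & res$isize > 0
  nPairs <- sum(keep)
  if (requireUnique) {
    mapq0 <- keep & !is.na(res$mapq) & res$mapq == 0
    if (any(mapq0))
      message(sprintf("uniqueness filter removed %d of %d fragments",
                      sum(mapq0), nPairs))
    keep <- keep & !mapq0
  }
  gr <- GenomicRanges::GRanges(as.character(res$rname[keep]),
        IRanges::IRanges(start = res$pos[keep],
                         width = res$isize[keep]))
  gr <- .filterInserts(gr, minInsert, maxInsert)
  sort(gr)
}

#' Read fragments from a plain BED3-style table
#'
#' Tab-separated chrom / start / end, 0-based half-open; the same filtering
#' contract as [readFragments()] is applied to the fragment lengths.
#'
#' @param path file path.
#' @param minInsert,maxInsert inclusive insert-size bounds in bp.
#' @return a [GenomicRanges::GRanges] of fragments.
#' @export
readFragmentTable <- function(path, minInsert = 40, maxInsert = 1000) {
  if (!file.exists(path)) stop("cannot read fragment table: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop(sprintf("malformed fragment table line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.numeric(p[2]))
    e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed fragment table line %d: non-numeric coordinates",
                   i))
    if (e <= s)
      stop(sprintf("malformed fragment table line %d: end <= start", i))
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  start0 <- as.numeric(vapply(parts, `[`, character(1), 2L))
  end0 <- as.numeric(vapply(parts, `[`, character(1), 3L))
  gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1, end = end0))
  sort(.filterInserts(gr, minInsert, maxInsert))
}

#' Write a nucleosome map as BED6
#'
#' One line per call: chrom, center - 73, center + 74 (a 147 bp footprint,
#' 0-based half-open), name \code{nuc<k>}, score equal to the landscape
#' height at the call scaled to [0, 1000], strand ".". Fractional centers
#' are rounded to the nearest base for output. Calls are written sorted by
#' chromosome, then start.
#'
#' @param map a [NucleosomeMap-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeNucleosomeMap <- function(map, path) {
  gr <- map@calls
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write nucleosome map to: ", path)
  on.exit(close(con))
  if (length(gr) == 0L) return(invisible(path))
  mc <- S4Vectors::mcols(gr)
  h <- mc$height
  rng <- range(h)
  score <- if (diff(rng) > 0) round(1000 * (h - rng[1]) / diff(rng))
           else rep(1000L, length(h))
  cen <- round(mc$center)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = cen - 73, end = cen + 74,
                   name = paste0("nuc", seq_along(gr)),
                   score = score, strand = ".")
  df <- df[order(df$chrom, df$start), ]
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED nucleosome map written by [writeNucleosomeMap()]
#'
#' Centers are recovered as BED start + 73.
#'
#' @param path BED file path.
#' @param nucSize non-overlap threshold recorded in the returned map.
#' @return a [NucleosomeMap-class].
#' @export
readNucleosomeMap <- function(path, nucSize = 146) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(.makeMap(NULL, nucSize))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   center = GenomicRanges::start(gr) - 1 + 73,
                   alpha = NA_real_,
                   height = if (!is.null(gr$score)) as.numeric(gr$score)
                            else NA_real_,
                   s = NA_real_, support = NA_integer_)
  .makeMap(df, nucSize)
}
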