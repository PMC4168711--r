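#' @include AllClasses.R AllGenerics.R synthetic.R consensus.R
NULL

# Deterministic per-replicate seed derivation: any single replicate of a
# sweep can be regenerated in isolation from the master seed, the condition
# index and the replicate index. Kept below 2^31 - 1.
sweepSeed <- function(masterSeed, condIdx, rep) {
  as.integer((as.numeric(masterSeed) * 1009 +
                condIdx * 104729 + rep * 7919) %% 2147483647L)
}

# Metrics shared by both sweeps.
.replicateMetrics <- function(map, called, threshold = 148) {
  pe <- positioningError(map, called)
  data.frame(
    nTrue = nNucleosomes(map),
    nCalls = nNucleosomes(called),
    nFiltered = filterCloseNucleosomes(called, threshold),
    nMatched = pe$nMatched,
    errMean = if (pe$nMatched) mean(pe$distances) else NA_real_,
    errSd = if (pe$nMatched > 1) sd(pe$distances) else NA_real_)
}

#' Sweep the fuzzy-nucleosome fraction
#'
#' For each fuzzy fraction r, generates \code{replicates} synthetic datasets
#' (grid of \code{scale * 1100} well-positioned slots with
#' \code{scale * (100 + 1000 r)} deletions and \code{scale * 1000 r} fuzzy
#' nucleosomes, coverage bound \code{maxCover}), runs the calling pipeline
#' and collects per-replicate call counts (raw and chain-filtered at 148 bp)
#' and positioning-error summaries.
#'
#' @param rValues fuzzy fractions in [0, 1].
#' @param replicates datasets per fraction.
#' @param scale linear scaling of the map size (1 = the full 1000-nucleosome
#'   benchmark; 0.1 = a 100-nucleosome desk version).
#' @param masterSeed master seed; per-replicate seeds are derived with
#'   [sweepSeed()].
#' @param config a [ProfileConfig-class] for the caller.
#' @param maxCover coverage bound passed to the generator.
#' @return data.frame with one row per (r, replicate).
#' @export
runFuzzySweep <- function(rValues = seq(0, 1, by = 0.1), replicates = 10,
                          scale = 1, masterSeed = 1,
                          config = ProfileConfig(), maxCover = 70) {
  stopifnot(replicates >= 1, all(rValues >= 0 & rValues <= 1))
  rows <- list()
  for (ci in seq_along(rValues)) {
    r <- rValues[ci]
    for (rep in seq_len(replicates)) {
      seed <- sweepSeed(masterSeed, ci, rep)
      sim <- syntheticNucleosomeMap(
        wpNum = round(1100 * scale), wpDel = round((100 + 1000 * r) * scale),
        fuzNum = round(1000 * r * scale), maxCover = maxCover, seed = seed)
      called <- suppressWarnings(callNucleosomes(sim$fragments,
                                                 config = config))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(r = r, replicate = rep, seed = seed),
        .replicateMetrics(sim$map, called))
    }
  }
  do.call(rbind, rows)
}

#' Sweep the sequencing depth by subsampling
#'
#' Subsamples a fixed fragment set at each fraction, reruns the caller and
#' reports call counts (and positioning errors when a truth map is given).
#' On well-behaved data the number of detected nucleosomes degrades
#' monotonically as reads are removed.
#'
#' @param fractions subsampling fractions in (0, 1].
#' @param fragments the full fragment set ([GenomicRanges::GRanges]).
#' @param trueMap optional [SyntheticMap-class] for accuracy metrics.
#' @param masterSeed master seed for the subsampling draws.
#' @param config a [ProfileConfig-class].
#' @return data.frame with one row per fraction.
#' @export
runCoverageSweep <- function(fractions = seq(0.2, 1, by = 0.1), fragments,
                             trueMap = NULL, masterSeed = 1,
                             config = ProfileConfig()) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  rows <- list()
  for (ci in seq_along(fractions)) {
    f <- fractions[ci]
    sub <- subsampleFragments(fragments, f,
                              seed = sweepSeed(masterSeed, ci, 1L))
    called <- suppressWarnings(callNucleosomes(sub, config = config))
    row <- data.frame(fraction = f, nFragments = length(sub),
                      nCalls = nNucleosomes(called),
                      nFiltered = filterCloseNucleosomes(called, 148))
    if (!is.null(trueMap)) {
      pe <- positioningError(trueMap, called)
      row$nMatched <- pe$nMatched
      row$errMean <- if (pe$nMatched) mean(pe$distances) else NA_real_
    }
    rows[[ci]] <- row
  }
  do.call(rbind, rows)
}

#' Summarise sweep results per condition
#'
#' Aggregates per-replicate rows into one row per condition: mean and sd of
#' the raw and filtered call counts and the mean positioning error. Every
#' summary is recomputable from the per-replicate table.
#'
#' @param results data.frame from [runFuzzySweep()] or [runCoverageSweep()].
#' @param by name of the condition column ("r" or "fraction").
#' @return data.frame with one row per condition.
#' @export
summarizeSweep <- function(results, by = intersect(c("r", "fraction"),
                                                   colnames(results))[1]) {
  header <- data.frame(condition = numeric(), n = integer(),
                       callsMean = numeric(), callsSd = numeric(),
                       filteredMean = numeric(), filteredSd = numeric(),
                       errMean = numeric())
  if (is.null(results) || nrow(results) == 0L) return(header)
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  out <- lapply(split(results, results[[by]]), function(g) {
    data.frame(condition = g[[by]][1], n = nrow(g),
               callsMean = mean(g$nCalls), callsSd = sd0(g$nCalls),
               filteredMean = mean(g$nFiltered), filteredSd = sd0(g$nFiltered),
               errMean = if ("errMean" %in% colnames(g))
                 mean(g$errMean, na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition), , drop = FALSE]
}

#' Write or read a sweep report as TSV
#'
#' @param x data.frame of per-replicate or summarised sweep results.
#' @param path output file.
#' @return \code{writeSweepTSV}: the path, invisibly; \code{readSweepTSV}:
#'   the data.frame.
#' @export
writeSweepTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSweepTSV
#' @export
readSweepTSV <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
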