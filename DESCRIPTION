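Package: nucleoscape
Title: Parameter-Free Multi-Scale Nucleosome Positioning from Paired-End MNase-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls nucleosome positions from paired-end MNase-seq (or
    sonicated ChIP-seq) alignments without requiring the user to choose a
    smoothing bandwidth. Each sequenced fragment is replaced by a Gaussian
    whose standard deviation scales with the fragment length; summing these
    over a grid of scale factors yields a family of nucleosome profiles,
    which are normalised against a low-resolution reference profile to give
    log-ratio nucleosome landscapes. Candidate nucleosomes are detected as
    landscape peaks at every scale, recentred on the centroid of their
    supporting fragment midpoints, and merged fine-to-coarse into a maximal
    set of non-overlapping calls. The package also ships a synthetic
    nucleosome-map generator (well-positioned and fuzzy nucleosomes) and the
    evaluation protocol used to benchmark positioning accuracy, call counts,
    and inter-nucleosome spacing periodicity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
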