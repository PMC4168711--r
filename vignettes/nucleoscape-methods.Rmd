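---
title: "Multi-scale nucleosome calling: model, parameters and design notes"
author: "nucleoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale nucleosome calling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

MNase digestion protects nucleosome-bound DNA; with paired-end sequencing
each template gives a fragment whose midpoint estimates a nucleosome dyad
and whose length carries information about digestion at that locus. The
central modelling idea is to let every fragment spread its evidence as a
Gaussian whose width scales with the fragment itself: fragment $i$ with
midpoint $\mu_i$ and length $w_i$ contributes density
$\mathcal{N}(x;\,\mu_i,\,\alpha w_i)$. The **profile** at scale $\alpha$ is

$$S_\alpha(x) \;=\; \sum_{i=1}^{n} \beta_i\,
  \frac{1}{\alpha w_i \sqrt{2\pi}}
  \exp\!\left(-\frac{(x-\mu_i)^2}{2(\alpha w_i)^2}\right),
  \qquad \beta_i = \frac{\gamma(w_i)}{n}.$$

Two consequences distinguish this from plain kernel density smoothing of
coverage: a long insert (uncertain dyad) is automatically smeared over a
wider interval at *every* scale, and a short, precisely placed fragment
stays sharp. Because very short fragments would otherwise produce the
tallest spikes, the weight penalty $\gamma(w) = \min(1, w/146)$ linearly
damps fragments below the nucleosome footprint and leaves longer ones at
weight $1/n$.

No single $\alpha$ fits a genome, so the caller evaluates a whole grid
$\alpha_1 < \dots < \alpha_m$ and normalises each profile by a very smooth
reference $S_A$ ($A$ larger than every grid scale):

$$N_\alpha(x) \;=\;
  \log\frac{S_\alpha(x) + \varepsilon}{S_A(x) + \varepsilon}.$$

The **landscape** $N_\alpha$ is a per-base log enrichment: it amplifies
concentrated structure in low-coverage regions and damps amplitude
differences caused by coverage and mappability, both of which affect
numerator and denominator alike.

On each landscape a *candidate nucleosome* is a pair $(q, s)$ with $q$ a
local maximum and $s$ its distance to the nearest local minimum. Landscape
peaks need not be symmetric, so each candidate is recentered on the
unweighted centroid of the fragment midpoints falling in its *basin* (the
interval between the two flanking minima — a partition, so every fragment
counts for at most one candidate per scale). The final map is assembled
greedily from the finest scale upward: a candidate is admitted only if it
is at least one footprint (146 bp, center-to-center, strict) from every
*other* candidate of its own scale and from every call already admitted;
admitted calls are never removed. Sharply positioned nucleosomes are thus
fixed early at high resolution, while fuzzy ones — whose fine-scale
evidence splits into mutually overlapping sub-peaks that disqualify each
other — are recovered later from smoother landscapes. One linear scan per
landscape finds the extrema, so the total work is $\Theta(m(n + l))$ for
$n$ fragments on a region of length $l$.

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `m` | 40 | — | number of scales; more scales refine the resolution ladder |
| `alphaRange` | [0.05, 0.63] | — | smoothing grid, equally spaced, endpoints included |
| `A` | 1.5 | — | reference scale; must exceed `max(alphas)` |
| `epsilon` | 1e-6 | profile units | log-ratio pseudocount |
| `nucSize` | 146 | bp | footprint: overlap threshold and $\gamma$ reference |
| `minInsert`, `maxInsert` | 40, 1000 | bp | inclusive insert-size filter |
| `truncation` | 6 | multiples of $\sigma$ | kernel support cutoff |
| `gammaFun` | min(1, w/146) | — | short-fragment penalty |

The grid bounds, $m$ and $A$ follow the published configuration of this
family of methods. $\gamma$ and $\varepsilon$ are not pinned down anywhere
in print; the linear ramp is the simplest nondecreasing penalty equal to 1
at the footprint, and $\varepsilon = 10^{-6}$ sits far below any attainable
profile value at realistic coverage (a single 146 bp fragment at the
coarsest useful scale contributes $\sim 10^{-3}/n$ at its midpoint), so it
only regularises exact zeros. Both are configurable in `ProfileConfig()`.

Insert bounds are inclusive: a 40 bp or 1000 bp fragment is retained,
39 and 1001 are not. "Uniquely mapped" is interpreted as: not secondary,
not supplementary, mapping quality > 0 — the multi-mapper convention shared
by common aligners, chosen so the filter is reproducible without
aligner-specific tags. Duplicate fragments are retained; MNase-seq coverage
is so deep that PCR-duplicate marking would also discard genuine biological
duplicates, and the published protocol does not deduplicate.

# Numerical choices

**Coordinates.** Intervals are 0-based half-open internally and in BED
output (`GRanges` objects use the usual 1-based representation at the
interface). Midpoints of odd-length fragments are half-integers and are
*kept fractional* everywhere — rounding them would bias centroids by half a
base systematically. Only BED output rounds centers to whole bases.

**Kernels.** Each Gaussian is tabulated once per (scale, rounded length,
sub-base phase) at integer offsets within $6\sigma$ and cached across
fragments and scales; the truncated mass is below $2\times10^{-9}$ per
fragment. Accumulation into the per-base track is a direct add in C++
(via Rcpp). Direct accumulation — rather than FFT convolution — is a
deliberate correctness choice: FFT noise ($\sim10^{-17}$) in zero-coverage
bases would later masquerade as strict local maxima on the log-ratio
landscape, whereas direct adds leave untouched bases at exactly zero.
Staggered truncated supports can still leave $\sim10^{-11}$-scale staircase
bumps in far-tail regions; these lie below the truncation's own mass
resolution, and the positive-height candidate rule (below) makes them
irrelevant downstream.

**Extrema.** Profiles are sampled at integer bases only, and one
run-length-compressed scan finds strict maxima and minima. A plateau
contributes a single extremum at its floored midpoint (deterministic and
unbiased); both region endpoints always count as minima, so widths $s$ and
basins are defined for edge peaks.

**Candidates must be enriched.** Only landscape maxima with strictly
positive height become candidates. In long zero-coverage gaps the log-ratio
equals $\log\{\varepsilon/(S_A + \varepsilon)\}$, which *mirrors* the
background profile and therefore has local maxima — with negative height
and no supporting reads — wherever $S_A$ dips. Without the sign rule the
greedy stage would admit these as isolated spurious calls in coverage
deserts and at deleted grid positions. Reading the landscape as an
enrichment distribution, a candidate below the smooth background is no
candidate; `detectPeaks(..., minHeight = -Inf)` restores the unfiltered
behaviour.

**Recentering before overlap checks.** The non-overlap guarantee must hold
for the *reported* positions, so candidates are recentered first and the
146 bp rule is applied to recentered centers. Within one scale, mutual
overlap disqualifies *both* peaks (they stay eligible at coarser scales);
survivors are processed left-to-right, which cannot change the admitted
set — admissibility within a set depends only on distances to other
same-set peaks and to earlier calls at least 146 bp away — but makes the
output byte-stable. A candidate whose basin contains no midpoints keeps its
raw position and is flagged with a warning.

**Degenerate inputs.** An empty fragment set yields an empty map; an empty
region or all-zero landscape yields no candidates; curves shorter than
three samples have no extrema.

# The synthetic benchmark

`simulateToy()` reproduces the minimal low-coverage scenario: 20 fragments
of 146 bp with midpoints $\mathcal{N}(300, 40)$ — a single fuzzy nucleosome
at ~20-fold coverage. `syntheticNucleosomeMap()` emulates the standard
simulator used to benchmark nucleosome callers: well-positioned nucleosomes
every `nucLen + linLen` bp (147 + 20 by default, the ~167 bp yeast-like
periodicity) with midpoint sd 30; a configurable number of grid deletions;
fuzzy nucleosomes at uniform random positions with midpoint sd 50,
explicitly allowed to overlap anything.

The simulator's per-nucleosome read-count law is not published; we draw
each count uniformly from $\{\lceil \mathrm{maxCover}/2\rceil, \dots,
\mathrm{maxCover}\}$ so that `maxCover` is an upper bound on per-nucleosome
coverage. Consequences worth knowing: on fuzzy-free maps per-base coverage
respects the bound (the test suite asserts $\le 1.2\times$), but where a
fuzzy nucleosome overlaps another, coverage stacks — with independent
counts per nucleosome that is unavoidable, and it matches the generator's
stated overlap semantics. The chromosome is sized tightly as
`wpNum * (nucLen + linLen) + linLen`; fragments falling outside it are
dropped.

What the generator does *not* emulate: sequence-dependent digestion bias,
GC/mappability structure, PCR duplicates, or mapping errors. Passing the
synthetic benchmarks therefore demonstrates the statistical machinery —
multi-scale detection, fuzzy-nucleosome recovery, non-overlap assembly —
not robustness to alignment artifacts, which is what the optional
real-data protocol in the README probes.

# Evaluation protocol

Positioning error matches calls to truths greedily by smallest center
distance, each item used at most once, capped at 100 bp; unmatched calls
and truths are counted separately. The cap makes "correspondence" concrete
where the benchmark leaves it loose; with truths at least 167 bp apart the
greedy matching coincides with the optimal assignment, and the suite
cross-checks this on small instances. Adjacent-call spacing is histogrammed
in 5 bp bins aligned at multiples of 5, and the mode is reported as the
modal bin center (167.5 for the bin containing 167). The over-reporting
filter chains consecutive calls with gaps $\le 148$ bp and counts each
chain once.

Sweep replicates derive their seeds deterministically from a master seed,
the condition index and the replicate index (`sweepSeed()`), so any single
replicate can be regenerated in isolation.

# Problem sizes

The default test and acceptance runs use a 1/10-scale fuzzy-free map
(110 grid positions, 10 deletions, coverage bound 70 — about 5,300
fragments over 18.4 kb), 100 toy replicates, and coverage sweeps over that
same map at fractions 0.2–1.0. These sizes give stable statistics
(100 calls, ~90 adjacent distances) in a few seconds per pipeline run;
the full-scale 1,000-nucleosome benchmark is a linear 10x extension of the
same generator and runs unchanged via `runFuzzySweep(scale = 1)`.

# Known limitations

* Calls are reported as fixed 147 bp footprints around the center; the
  method estimates centers, not footprint boundaries, and `s` is
  bookkeeping only — it plays no role in selection.
* The non-overlap rule is hard: genuinely overlapping nucleosome
  configurations (common among fuzzy nucleosomes) are represented by a
  single call, which is why call counts drop as the fuzzy fraction grows.
* The weight $\beta_i$ uses the per-region fragment count $n$; landscapes
  are invariant to this choice (numerator and denominator share the
  factor), but exported raw profiles from different regions are not on a
  common scale.
* No control track, significance testing or FDR control: every admitted
  candidate is reported.
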