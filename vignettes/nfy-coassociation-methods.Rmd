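---
title: "Methods: co-association analysis of the NF-Y regulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-association analysis of the NF-Y regulome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

NF-Y is a trimeric transcription factor that binds the CCAAT box with high
sequence specificity. Large ChIP-seq compendia show that many other
transcription factors and cofactors occupy the same genomic neighborhoods,
either because they read the CCAAT element through NF-Y, because they bind
their own motif at a fixed spacing from it, or because they co-occupy
regions without any CCAAT involvement. This package implements, as tested
and reusable code, the statistical pipeline for dissecting those
relationships from peak-summit data: replicate curation, a Poisson
summit-overlap co-association statistic, CCAAT motif enrichment with a
global/local distinction, motif-to-CCAAT spacing analysis, a four-group
partner classification, chromatin-state and target-gene annotation, and
pairwise Fisher statistics of co-regulation after NF-Y knockdown.

Everything is exercisable end to end on synthetic data with planted ground
truth; real narrowPeak/BED/JASPAR/TSV inputs are consumed through the same
readers.

# The co-association statistic

For an ordered pair of peak sets $(a, b)$ the statistic counts the summits
of $a$ falling within 300 bp windows centered on the summits of $b$ — i.e.
a maximum summit distance of 150 bp, bounds inclusive; each summit of $a$
counts at most once however many $b$ summits are nearby (the count then
reads directly as a share of $a$'s peaks). Significance uses a Poisson
null in which the genome offers $N$ equally likely 150 bp accessible slots
(the DNaseI-hypersensitive estimate, $N = 250{,}000$ by default), so the
expected overlap is

$$\lambda = \frac{n_a\, n_b}{N}.$$

The null distribution and $N$ are stated by the underlying method; the
occupancy form of $\lambda$ is the package's reconstruction — it is the
only two-set expectation consistent with that background. The upper tail
$P(X \ge k)$ is used when $k \ge \lambda$, the lower tail with a negated
final score when the overlap is depleted. p-values are Bonferroni-corrected
(universe = the number of ordered pairs evaluated in the run, recorded in
the output), clamped below at the smallest positive subnormal double
($2^{-1074}$), and reported as the signed $-\log_{10}$. The clamp gives the
finite integer score ceiling of $\lfloor -\log_{10} 2^{-1074} \rfloor =
323$ wherever the tail underflows — notably for any set against itself.

A pair is *significant* when the score strictly exceeds 100 **and** the
anchor (NF-YB) shares more than 10% of its peaks with the factor; both
inequalities are strict.

The anchored mode restricts both factors to summits within the window of
the anchor's summits and uses the anchor's peak count as $N$; an empty
restriction yields a degenerate zero-score result rather than an error
mid-pipeline.

Score matrices are clustered with distance $1 - r$ (Pearson correlation of
score rows) and centroid linkage. Centroid linkage over a correlation
distance is not geometrically well-founded (it is defined for squared
Euclidean distances) — it is implemented exactly as specified because it is
the procedure the downstream heatmaps assume, and average linkage is
available through the `method` argument. Rows are pre-sorted by factor
name so leaf order is deterministic under ties; constant rows carry no
correlation information and are dropped with a warning.

# Replicate curation

Stages, in order: (1) treated experiments are split into a side channel
(they are analyzed per dataset downstream, so one biological factor can
appear in several groups); (2) tagged-protein duplicates are removed when
an untagged experiment exists; (3) "minima" — replicates with fewer than
10,000 peaks or fewer than half the peaks of the next-larger replicate —
are discarded; (4) the surviving group is kept only if some replicate pair
exceeds 66% summit concordance, and then the member with the most peaks
represents the factor. Unique experiments bypass stages 3–4.

The concordance metric itself is not fixed by the thresholds, so the
package defines it on the smaller replicate: the share of the smaller
set's summits within 150 bp of some summit of the larger. That is the most
conservative symmetric choice and keeps one window convention across the
whole pipeline (the alternative — interval-based overlap — would introduce
a second geometry for no gain).

# Motif enrichment: global, local, and the CCAAT classes

Windows are 150 bp, summit-centered, matching the co-association window.
Scanning is log-odds on both strands with a pseudocount of 1% of the
column total per cell (avoiding $-\infty$ on zero counts), min-max
normalized per matrix so a consensus match scores exactly 1 and the
anti-consensus exactly 0. Ties prefer the plus strand, then the leftmost
offset.

The external tool that inspired the global/local semantics does not
publish its internal statistic, so both tests are reconstructions of the
verbal definitions and are flagged as such:

* **global**: one-sided z-test that the mean best score in peak regions
  exceeds the mean over an accessible-region background, using the
  background variance (an exact resampling alternative is available when a
  full background sample is supplied);
* **local**: one-sided paired t-test of the central best score against the
  mean of the two immediately flanking windows of the same width.

Both are called significant below $10^{-10}$. The CCAAT class of a factor
is then: `global_primary` if the CCAAT matrix is globally significant and
top-ranked among all matrices tested, `global_secondary` if globally
significant but outranked (typically by the factor's own motif),
`local_only` if only the flank contrast is significant, `none` otherwise.

# Positional bias

In regions co-bound by the anchor and the factor, the best CCAAT hit is
located (regions scoring below 0.8 normalized are excluded and counted);
the reference point is the middle A of the CCAAT pentanucleotide inside
the matched window, found from the matrix consensus and orientation
corrected. The signed distance is (partner-motif center) − (middle A) on
the CCAAT-defining strand, negative meaning the partner sits 5′ of CCAAT.

Two numerical choices matter here. First, partner hits whose motif window
overlaps the matched CCAAT window are excluded — on synthetic consensus
plants such "hits" are the CCAAT sequence itself rescored by the partner
matrix and produce a deterministic spike; the same offsets are removed
from the null support. Overlapping-site geometries (factors whose own
element contains the CCAAT core) are therefore outside this statistic, a
documented limitation. Second, the non-uniformity test is a chi-square of
the offset histogram against a null that is uniform *per region* over that
region's attainable non-overlapping offsets, with contiguous support bins
aggregated until each expects at least five counts, so the approximation
holds at modest region counts. Under per-region uniform placement the
p-value is calibrated (checked by simulation in the test suite); planted
spacings of −10/−11/−12 bp are recovered exactly at plant fraction 1 and
within ±1 bp at fraction 0.3.

# The four groups

Combining enrichment class with overlap shares (factor share = fraction of
the factor's peaks overlapping NF-YB; NF-YB share = the reciprocal):

| Group | CCAAT enrichment | share rule |
|---|---|---|
| 1 | global (primary or secondary), any cell line | factor share > 20% in some cell line |
| 2 | any class, any cell line | factor share in (5%, 20%] |
| 3 | any class | max factor share ≤ 5% |
| 4 | none anywhere | NF-YB share > 10% with score > 100 in some cell line |

Boundaries are fixed by precedent: a factor at exactly 20% belongs to
Group 2, the borderline 5% overlap belongs to Group 3 (with the factors
that avoid the anchor), and the 10% NF-YB-share rule is strict. The
"any cell line" quantifier applies to Groups 1, 2 and 4; Group 3 bounds
the maximum so single-cell-line factors classify consistently. Treated
datasets are classified per dataset.

# Annotation and co-regulation

Summits map to 200 bp segmentation bins under the half-open convention (a
summit on a boundary belongs to the bin starting there). Promoter windows
are strand-oriented and inclusive at both ends: (−1000, +100) around the
TSS for target-gene assignment, (−450, +50) for promoter TFBS work.
Pathway over-representation is a one-sided hypergeometric test (the
original pipeline delegated this to an external web service; the statistic
here is an in-package reconstruction); surviving pathways need some factor
below $10^{-5}$ and a background of at most 200 genes, where "background"
is the pathway's full gene count — the stricter of the two readings of
that filter. Pathways with identical gene sets merge into the most general
one, defined as the largest background (ties lexicographic), with merged
ids kept as provenance; the result is invariant to input order.

DEGs use strict thresholds (FDR < 0.01, |log2FC| > 1; genes exactly at a
threshold are neutral, missing FDR is neutral). Pairwise co-regulation is
a two-sided Fisher exact test (point-probability method) on the 2×2 of
membership in two factors' regulated sets; the universe is the state's DEG
set (the UP universe for UP tests), which is the reading most consistent
with conditioning on "the total number of genes regulated" — a
whole-annotation universe can be passed explicitly instead. Sidedness is
not dictated by the source procedure; two-sided is the conventional
default and is recorded in output metadata. The −log10 transform uses the
same subnormal clamp as co-association, and the UP/DOWN matrices are
clustered by the same Pearson/centroid routine.

# The synthetic cosmos

The generator produces every input with planted structure, under one
global seed fanned out to per-stage child seeds:

* **genome**: equal-length chromosomes with disjoint 150 bp accessible
  regions placed uniformly by the spacing method, kept ≥ 101 bp apart so
  that the ±50 bp summit jitter can never bridge two distinct regions —
  planted overlap fractions are then recovered *exactly*, not only in
  expectation;
* **peak sets**: summits at accessible-region centers with uniform ±50 bp
  jitter (two summits planted in one region are ≤ 100 bp apart, inside the
  150 bp window with margin); pairwise planted fractions are satisfied
  sequentially, factor $j$ drawing its shared summits from each earlier
  factor's regions and its free summits from untouched regions;
* **sequences**: i.i.d. uniform background (the simplest null for score
  calibration), CCAAT consensus planted with its middle A at the region
  center, partner consensus at the stated signed offset and orientation;
* **DEG tables**: exact planted UP/DOWN counts clearing the strict
  thresholds, and per-factor target sets with planted pairwise overlaps.

The demo cosmos (`run_demo()`) has three "cell lines", an NF-YB anchor of
3,000 summits and twelve partner factors of 1,500 summits each — three per
group, with shares 50/30/90%, 12/15/19%, 1/2/3% and 35/30/40% — plus a
tagged duplicate, a concordant second replicate, a minima replicate and a
treated dataset for the curation stage, and a planted −11 bp spacing for
one Group 1 factor. Motif enrichment runs on separate small sequence
genomes (250 scanned regions per factor, 300 background regions per cell
line, basal CCAAT rate 30% in accessible background — the rate at which the
local-only archetype plants centrally, chosen so the flank contrast is
unambiguous while the global contrast stays null); the curation peak-count
floor is scaled to the cosmos (a third of the per-factor peak count).
These sizes complete the demo in well under a minute on one CPU and were
chosen as the smallest cosmos in which every planted effect is recovered
with wide margins.

What passing tests show — and do not. The generator plants consensus
motifs in uniform background, uses equally likely accessible slots, and
jitters summits independently; real ChIP-seq has degenerate motif matches,
GC and mappability structure, peak-width heterogeneity and correlated
binding far richer than pairwise fractions. Recovery on this cosmos
validates the *statistics and their calibration*, not the biology of any
particular dataset.

# Degenerate inputs and tie-breaks

Missing narrowPeak summit offsets (−1) fall back to the interval midpoint
(floor). Chromosome names are compared as exact strings — silent "chr"
aliasing hides data errors. Peaks are unstranded everywhere; strand is
honored only in promoter windows and motif scanning. Duplicate summit
positions within one file are kept (their handling upstream is unknowable
from the inputs). Empty anchored restrictions yield degenerate zero
results; empty replicate sets, all-constant matrices, empty gene universes
and absent CCAAT matrices are errors. Consensus ties in a PFM column
resolve to the alphabetically first base.

# Known limitations

* The global/local enrichment statistics and the ORA are reconstructions
  of tools whose internals are not published with the procedure; absolute
  p-values will differ from those tools even where calls agree.
* The positional-bias statistic does not see overlapping-site geometries.
* Centroid linkage with correlation distance can produce inversions
  (non-monotone merge heights); the dendrograms are reported as computed.
* The sequential planting scheme satisfies pairwise fraction matrices of
  the star and block designs used here; arbitrary joint overlap systems
  may be infeasible and are rejected with an error rather than
  approximated.
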