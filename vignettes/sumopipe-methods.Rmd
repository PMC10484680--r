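---
title: "Methods: models, parameters and design choices in sumopipe"
author: "sumopipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sumopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumopipe)
```

# Scope

`sumopipe` re-implements, as a tested and reusable pipeline, the
computational analysis used to study how the chemotherapeutic
daunorubicin (DNR) strips SUMO-conjugated proteins off chromatin in
acute myeloid leukemia cells, and what that does to regulatory elements,
to the SUMOylome, to gene expression and to 3D contacts of a drug-induced
locus. Seven coupled stages are covered: threshold peak calling on signal
tracks, promoter/enhancer annotation from histone marks, interval algebra
and gene-list crossing, a 4C-seq viewpoint pipeline, SILAC SUMOylome
classification, a compact negative-binomial differential expression
stage, and a synthetic-data generator that plants ground truth for all of
them. Read alignment, spectral searches, motif discovery and enrichment
analyses are intentionally out of scope.

# Peak calling on fixed-bin tracks

`callPeaks()` reproduces interactive genome-browser thresholding: a bin
is signal when its value strictly exceeds `valueThreshold`; signal runs
separated by sub-threshold stretches of at most `maxGap` bases are
bridged; assembled peaks must span strictly more than `minRun` bases.
The SUMO-2/3 ChIP-seq defaults are threshold 32, max gap 100, min run
100; CTCF CUT&RUN profiles use threshold 360 with both run parameters at
50.

Three conventions deserve a note:

* **Units.** Gap and run are measured in bases, not bins, so the
  parameters do not change meaning when the track bin size changes.
  With 50 bp bins, a 100 bp gap is two bins.
* **Ties.** A bin exactly at the threshold is below it. Thresholding is
  exceedance (`>`), matching the strict comparators in the parameter
  conventions ("Min Run > 100").
* **Peak statistics.** `meanValue` averages every bin inside the peak
  span, bridged gap bins included, because the peak is reported as one
  contiguous interval.

The caller is verified against a brute-force oracle that enumerates
every maximal qualifying bin set, exhaustively for all short
above/below patterns and on random 200-bin tracks.

# Promoters, enhancers, activity

Promoters are the 2 kb upstream of each TSS. In 0-based half-open
coordinates a plus-strand TSS *t* gives `[t - 2000, t)` and a
minus-strand TSS gives `[t, t + 2000)`; the one-base asymmetry between
strands follows the stated interval convention rather than a strict
mirror image, and is documented here so coordinate comparisons are
reproducible. Promoters are kept for every annotated gene; H3K4me3
overlap is recorded as a support flag rather than used as a filter.
H3K4me1 peaks that do not overlap any promoter — by even one base —
are candidate enhancers; partially overlapping peaks are excluded whole,
keeping peaks atomic instead of trimming them. Activity of either
element class is presence of an H3K27ac overlap of at least one base;
no minimum-overlap fraction is imposed because none is part of the
contract, but the threshold is configurable at the call sites that
consume it. RNAPII/H3K4me3 "high/low" stratification is likewise an
overlap flag, not a quantitative cutoff.

Metaprofiles average strand-oriented windows around anchors (TSSs) and
drop anchors whose window leaves the covered chromosome, reporting the
count. Heatmap matrices bin each region window per track and sort rows
by decreasing mean of the ranking track with a stable sort, so ties
keep input order and repeated runs are identical.

# 4C-seq viewpoint pipeline

## Fragment map

`digestGenome()` cuts at every occurrence of the first-enzyme site
(NlaIII-style `CATG`, cut after the site) and flags fragments blind when
no second-enzyme site (DpnII-style `GATC`) is fully contained in them.
Both sites and the cut offset are configurable; the defaults follow
standard enzymology for that enzyme pair. Fragments tile each chromosome
exactly — the test suite reconstructs 100 random genomes byte-for-byte
from their fragment sequences.

## Reads: trim-capture, placement, assignment

Reads carrying the viewpoint amplification sequence
(`CGTGACGCACGGAAACGTC`) are kept, everything through the end of the
viewpoint-side `CATG` is trimmed away, and the remaining ligated partner
sequence is placed by exact match of its 5' 20-mer on the forward strand
of the synthetic genome. Exact-match placement deliberately replaces a
short-read aligner: synthetic genomes are random, so 20-mers are
essentially unique, and alignment is not the analysis contract under
test. Ambiguous and unplaced reads are counted and excluded; if more
than half the reads are ambiguous the genome is too repetitive for the
chosen k and the function stops with guidance. Every stage preserves
read accounting (`kept + dropped + empty = input`, `assigned = placed`),
which the acceptance suite asserts.

## Normalization

The viewpoint fragment and its two neighbours on each side are excluded
(undigested and self-ligation products concentrate there; the window is
configurable), and remaining counts are scaled to reads per million
included reads. Blind fragments stay in the normalization universe by
default — excluding them is available as a mode, since practice varies —
and the normalization universe is genome-wide; synthetic genomes are
single-TAD scale, so a cis-only restriction would be a no-op here.

## Interaction calling

The caller implements a replicate-consistency contract: a fragment is
part of an interaction only when it is significant at `alpha = 0.05` in
*every* replicate, and significant fragments are merged (bridging at
most one intervening fragment) into regions labelled with roman
numerals. Per replicate:

1. Normalized scores of each viewpoint arm are smoothed with a running
   median over 21 fragments, each arm ordered by distance from the
   viewpoint. Smoothing per arm matters: the running median of a
   monotone decay is unbiased at every position, whereas smoothing
   across the viewpoint peak in position space systematically
   underestimates the near-viewpoint background and manufactures false
   positives there.
2. A monotonically non-increasing background in fragment-index distance
   is fitted to the smoothed scores by isotonic regression, pooling
   both arms.
3. Residuals are variance-stabilized on the square-root scale — scores
   derive from counts, so their variance grows with the mean, and
   without stabilization near-viewpoint fragments dominate the ranks of
   their stratum.
4. One-sided exceedance p-values are ranks against same-distance-stratum
   residuals (strata of about 50 fragments along increasing distance).
   The reference set of each stratum is first cleaned of gross outliers
   (above median + 3 MAD) so that a genuine multi-fragment interaction
   does not suppress the ranks of its own members.

Two guard rules keep the null honest. Fragments closer to the viewpoint
than the smoothing half-window have end-rule-extrapolated backgrounds
(a linear extrapolation cannot follow the convex 1/d decay) and are
treated as background only, never called — in line with the common
practice of excluding a viewpoint vicinity from testing. And regions
supported by fewer than two significant fragments are dropped: a real
contact spreads over neighbouring fragments, while an isolated
single-fragment signal repeating across replicates is more often a
shared amplification artifact. Under the generator's study conditions
(30 000 reads per replicate, three replicates, planted 4-fold
enrichments over 5-fragment regions) the caller attains sensitivity 1.0
with a null false-call rate below 1 % across seeds.

## Differential contacts

Raw fragment counts are summed per region and replicate; sequencing
depth is each profile's total included reads (scaled to geometric mean
1); the NB stage below supplies the test, with BH correction across
regions. Because scores are per-million, a strong gain in one region
necessarily shifts the shares of the others slightly; differential
results should be read as changes in contact share, which is also how
the underlying assay behaves.

# SILAC SUMOylome classification

Per paralog (SUMO-1, SUMO-2/3), up- and down-modified sets are proteins
with log2 ratio strictly above +0.5 or strictly below −0.5, restricted
to the SUMOylated universe established in the baseline
characterization. Proteins outside the universe are never classified,
missing ratios are skipped and counted, and set accounting reports
|A|, |B|, |A∩B| and |A∪B| with the inclusion–exclusion identity
asserted. A ratio-only rule is implemented — no significance filter is
layered on top, since none is part of the contract — but the table
accepts extra columns, so a p-value hook costs nothing. The abundance
guard flags (never removes) hits whose input-proteome ratio also moved
beyond the cutoff.

# Differential expression stage

This stage supplies the fold-change/FDR filter and the NB test reused by
the 4C differential step. It is a deliberate simplification of full NB
frameworks, and the vignette states exactly where:

* size factors are plain median-of-ratios (verified identical to the
  reference implementation on random matrices);
* per-gene dispersions are method-of-moments estimates from pooled
  within-group variances, shrunk in log space (weight 0.5) toward a
  trend `a0 + a1/mu` fitted across genes — no Cox–Reid adjustment;
* the Wald statistic on the log2 ratio of normalized condition means
  (pseudocount 0.5 for finiteness) is referred to a t distribution with
  `(n1 + n2 - 2) / (1 - shrink)` degrees of freedom. The inflation
  credits the trend's contribution to the dispersion estimate, the same
  logic as prior degrees of freedom in moderated-t frameworks: with the
  default shrink of 0.5, a 3-vs-3 design tests on 8 df. Under null
  simulations at dispersions 0.02–0.2 this yields empirical type-I
  error of 0.045–0.06 at nominal 0.05, where an unmoderated normal
  reference is anticonservative (~0.08–0.10) and a 4-df t is
  conservative (~0.02);
* no fold-change shrinkage: planted log2 fold changes of 2 are
  recovered with median error well inside ±0.3 at 3 vs 3.

DEGs are genes with linear fold change ≥ 2 (or ≤ 1/2) — inclusive —
and BH-adjusted p strictly below 0.05. The "≤ 2-fold down" reading is
implemented as linear FC ≤ 0.5; a signed convention would double-count
the boundary and is not used, though the filter takes any threshold.
BH adjustment is the hand-written step-up with monotonicity
enforcement, tested against both a literal-formula oracle and the
standard library implementation. The four-contrast comparison ladder
(drug vs mock, inhibitor vs mock, combination vs mock, combination vs
drug) is exercised on synthetic counts, and the SUMO-dependence filter
("response altered at least 2-fold by the inhibitor") defaults to the
direct combination-vs-drug contrast; the ratio-of-fold-changes reading
is available as a mode.

# The synthetic-data generator

Every generator is a pure function of the configuration and its seed;
each one derives a private RNG stream from the master seed, so stages
can be regenerated independently and full runs are byte-identical. The
defaults are the study conditions all tests run under:

* one 200 kb chromosome (single-TAD scale) of uniform base composition,
  so `CATG` occurs at the expected 1/256 rate (~780 fragments);
* 25 genes with 2 kb promoters and 8 enhancer elements; rectangular
  (boxcar) signal peaks of height 64 centred 100 bp upstream of TSSs
  and at enhancer centres, over Poisson(2) background noise at 50 bp
  bins; 70 % of elements active; CTCF co-placed at one third of SUMO
  peaks;
* a DNR condition sharing the mock background with planted peaks scaled
  by 0.5, so a depletion factor of 1 gives identical tracks by
  construction;
* 30 000 4C reads per replicate from a power-law contact decay
  (exponent −1 on fragment-index distance) with three planted
  5-fragment regions (a stable one, one lost under DNR, one gained)
  and 20 % decoy reads lacking the capture;
* the published per-paralog SILAC set sizes (31/11/8 up, 83/32/19 down)
  planted in a 894-protein universe, hit ratios drawn at least 0.15
  beyond the ±0.5 cutoff and background ratios truncated inside ±0.45,
  so planted sets are exactly recoverable — plus 20 out-of-universe
  contaminants and two deliberately abundance-confounded hits;
* NB counts (dispersion 0.05, lognormal baselines, depths 0.7–1.4)
  with 25 up and 25 down genes at log2 fold change 2 in a 500-gene
  expression universe.

What passing tests show — and what they do not: the generator emulates
the *statistical structure* of the real assays (peaked tracks at
cis-regulatory elements, condition-dependent depletion, viewpoint decay
with planted contacts, bimodal ratio tables, overdispersed counts), not
their biology. Boxcar peaks have no shape variation, reads have no
sequencing errors or quality structure (non-goals), the genome is a
single uniform-composition chromosome, and planted effects are clean.
Passing therefore demonstrates that the algorithms implement their
contracts and recover planted truth under realistic noise models; it
does not certify performance on real libraries, where alignment,
mappability, GC structure and batch effects intervene upstream.

# Pipeline orchestration

`runPipeline()` executes simulate → peak calling → annotation →
crossing → 4C → SILAC → DE → gene-list crossing from a nested
configuration (YAML or list) with unknown keys rejected. All analysis
inputs are read back from the files the simulation stage wrote, so
stages are coupled only by file contract, and identical configuration
plus seed gives byte-identical outputs (asserted by checksum in the
tests). A stage failure halts downstream stages; partial outputs stay on
disk and the report labels the failed stage. The report includes
sensitivity/precision per stage against the truth manifest. Problem
sizes in the bundled test configurations (50 kb genome, 5 000 reads, two
replicates) are chosen to exercise every code path in seconds; the
acceptance checks run the 4C caller at the full study conditions
(30 000 reads × 3 replicates × 50 seeds).

# Known limitations

* Exact-substring read placement is forward-strand only and requires a
  genome whose fragment-start k-mers are unique at the chosen k — by
  design sufficient for synthetic genomes, not a general aligner.
* The NB stage's dispersion trend is a two-parameter least-squares fit;
  with very few features (e.g. a handful of 4C regions) it degrades to
  a near-constant prior, which is why region-level contact tests are
  best read at the reported FDR, not as exact p-values.
* The interaction caller cannot call contacts closer to the viewpoint
  than the smoothing half-window (about 12 fragments by default); this
  zone is excluded from testing, not from normalization.
* Interval operations ignore strand throughout (peaks are unstranded);
  promoter orientation enters only through window construction.
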