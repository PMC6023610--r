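---
title: "Methods: stage-resolved TALE occupancy, motif modes and chromatin classes"
author: "TALEreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved TALE occupancy, motif modes and chromatin classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TALEreg)
```

# Overview

`TALEreg` analyses how TALE-family transcription factors (Prep, Pbx, Meis)
occupy the genome at two embryonic stages and how that occupancy relates to
DNA motif content, chromatin state and gene expression. The package works on
standard text formats (narrowPeak, bedGraph, BED, FASTA, TSV) and every
stochastic step is seeded, so analyses are reproducible to the byte.

This vignette documents the procedures, the parameters that matter, the
synthetic-data model used for testing, and the numerical and design choices
that were genuinely open.

# Peak dynamics

A peak is an interval with a single-base **summit** (position of maximal
enrichment) and a **fold enrichment** (FE) over input. The analysis set is
defined by `filterByFoldEnrichment(x, minFE = 10)`; the boundary is
inclusive, matching the standard "FE >= 10" phrasing of the cutoff. All coordinates are
handled 1-based inside R (the GenomicRanges convention) and converted at the
file boundary: narrowPeak/bedGraph/BED are 0-based half-open on disk, and the
narrowPeak summit column (offset from interval start, -1 allowed and then
replaced by the interval midpoint) is converted to an absolute position on
read.

Two peaks **colocalize** when their summits are within
`maxSummitDist = 50` bp, inclusive. Each peak counts once no matter how many
partners it has; `colocalize()` additionally returns every qualifying pair.
The **late-only** population is obtained by `stageOnly(late, earlyUnfiltered)`
— subtraction is performed against the early peak set *before* FE filtering,
so that a late peak is only called late-only if no early binding evidence of
any strength lies within the colocalization distance. This makes
`stageOnly()` and `colocalize()` exact complements on the late set, a
property the test suite asserts for arbitrary inputs.

`nearestSummitDistance()` uses per-chromosome sorted summit vectors with
binary search (`findInterval`), O(n log m); the brute-force all-pairs scan is
kept in the tests as an independent oracle. `fractionWithin(d, 40000)`
reports the percentage of query peaks whose nearest reference summit is
within 40 kb; queries on chromosomes with no reference peak have distance
`NA` and remain in the denominator, so the percentage is over *all*
late-only peaks rather than only those with a same-chromosome reference.

`randomCoordinates()` draws baseline intervals with chromosomes weighted by
length and uniform starts, for conservation- or association-style controls.

# Motif analysis

Motifs are IUPAC consensus strings in a small registry
(`defaultMotifRegistry()`):

| name    | consensus    | role                                            |
|---------|--------------|-------------------------------------------------|
| DECA    | `TGATTGACAG` | Prep:Pbx dimer site (adjacent half-sites)       |
| HEXA    | `TGACAG`     | monomeric Prep/Meis site; *excluded by DECA*    |
| PBXHOX  | `TGATTTAT`   | Pbx:Hox dimer site                              |
| PBXHOX_halfsite | `TGATNNAT` | generic Pbx half-site arrangement        |
| NFY     | `CCAAT`      | NF-Y pioneer-factor box                         |
| SPKLF   | `CCMCRCCC`   | Sp/Klf family site (M = A/C, R = A/G)           |
| ATRTTAA | `ATRTTAA`    | AT-rich site of unassigned factor               |

Scanning is by regular expression on both strands: the consensus is expanded
to character classes, all (possibly overlapping) forward matches are found
with a zero-width lookahead, and the reverse complement of the consensus is
scanned the same way, reporting reverse-strand hits in forward coordinates.
An `N` in the *subject* (assembly gap) is matched only by the motif code `N`
— a conservative choice so gaps never satisfy informative positions. A
position matching on both strands (palindromes) yields two hits, but
presence is boolean, since the quantity of interest is "sequences containing
at least one occurrence".

**Exclusion rule.** HEXA is a substring of DECA, so naive counting would call
every DECA window HEXA-positive. `motifPresence()` therefore supports a
sequence-scoped exclusion: HEXA counts only in sequences containing no DECA
match anywhere in the window (not merely non-overlapping ones). The scope is
the whole window because the biological claim is about which *site class* an
element belongs to, not about individual matches.

Prevalence (`motifPrevalence()`) is evaluated on 200 bp summit windows
(`[summit - 100, summit + 100)`, clipped at chromosome ends with a warning).
This package standardizes on the 200 bp window for prevalence, the same
convention used everywhere else in the analysis.

Between-population enrichment (`enrichmentBetween()`) uses a two-sided
Fisher's exact test on the 2x2 presence/absence table, reporting the sample
odds ratio with the Haldane 0.5 correction when a cell is zero. Rank-sum
enrichment over scored sites (the AME approach) needs a scoring model that
a consensus string does not provide; Fisher on presence calls is the
natural test for presence-fraction data and is exactly testable against
hypergeometric enumeration.

`motifSpacing()` reports, per sequence containing both motifs, the minimum
absolute center-to-center distance over all hit pairs (centers are
`start + (length - 1)/2`, so even-length motifs get half-integer centers; bin
widths absorb the half-base ambiguity in offset histograms).
`summitOffsetProfile()` bins signed motif-center-minus-summit offsets.

# Signal matrices and chromatin classes

`computeMatrix(track, peaks, flank, bin)` reproduces reference-point signal
matrices: for each peak, `2*flank/bin` consecutive bins tile
`[summit - flank, summit + flank)`; the bin value is the **mean** track value
over the bin (scale-invariant to bin width, matching "average signal"
semantics), with bases beyond the chromosome end contributing zero and such
rows flagged rather than dropped, so row order is preserved for the
classifier. The defaults are flank 1000 bp and bin 25 bp (80 columns). The
zero-fill contract for out-of-range bases is this package's definition,
asserted by a mass-conservation test (sum of bin means x bin width equals
the track integral over fully covered windows).

`log2Change(t2, t1, pseudocount = 1)` is the cell-wise
`log2((v2 + pc)/(v1 + pc))`. Tracks are non-negative with many zeros, so a
pseudocount is required; 1.0 is the package default, and the limit
behaviour is tested with a tiny pseudocount.

Classification is two-level:

1. `assignMpad()` clusters rows of the H3K4me1 matrix with k-means
   (`k = 4`) and ranks clusters by mean row signal. Clusters whose mean is
   below `lowFraction = 0.25` of the top cluster's mean are **non-MPAD**; if
   no cluster falls below the cutoff the single lowest-mean cluster is
   non-MPAD. The expected topology is three marked clusters plus one unmarked
   cluster holding ~75% of sites; the relative cutoff reproduces that
   topology on any input, and the fallback keeps the rule total. An all-zero matrix is
   all non-MPAD by definition.
2. `assignClasses()` clusters MPAD rows on the column-concatenated
   `[H3K27ac | H3K27me3]` matrix and labels clusters **Class1..Class4** by
   mean H3K27ac descending, ties broken by mean H3K27me3 ascending (so the
   repressed, H3K27me3-high group lands in Class 4). Whether the original
   clustering used both marks jointly or H3K27ac alone with H3K27me3
   displayed could also be done per mark; joint clustering is this package's definition,
   since the class semantics depend on both marks.

K-means uses Lloyd iterations on **raw** (unscaled) bin values with
k-means++ seeding and `restarts = 10`, keeping the best run by total
within-cluster sum of squares; the seed makes it deterministic.
Standardization is deliberately avoided: the MPAD/non-MPAD contrast *is* a
scale contrast, and standardizing columns would erase it. Final labels
depend only on cluster statistics (means), never on raw cluster indices, so
they are invariant to label permutation and, on separated data, to the seed.

# Gene association, expression and enrichment

`associatePeaksToGenes()` links peak p and gene g when the TSS is within
`window` bp (5 kb or 30 kb, inclusive) of the **peak center**
(`floor((start0 + end0)/2)`, the windowed-association convention of the
source protocol, which anchors on centers rather than summits).
Many-to-many links are kept.

`deFilter()` applies `padj <= 0.01` and linear fold-change magnitude
`>= 1.5`, both inclusive, splitting by direction. Differential expression is
an *input* table — model fitting is out of scope — and the synthetic module
emits one computed from its ground-truth means.

`classExpressionSummary()` computes, per gene linked to a class,
`log2(mean TPM + 1)` across the selected samples (or a log2 ratio of two
sample-group means for the fold-change variants), then a global
Kruskal–Wallis test across classes and pairwise **Dunn** post-hoc tests. The
Dunn z statistics use mean ranks of the pooled sample with the standard tie
correction; p-values are two-sided normal with Bonferroni adjustment (the
simplest defensible correction). No installed
package provides Dunn's test, so it is implemented here and verified against
hand-computed rank statistics. Classes with fewer than two genes are
excluded from testing and reported. A gene near peaks of several classes
contributes to each class — the association is genuinely many-to-many and
collapsing it would hide mixed-class loci.

`enrichmentVsRandom()` formalizes "enrichment above a random set of genes" as
a permutation test: the observed overlap of the target set with the
peak-associated set is compared to overlaps of `nPerm` uniform draws of the
same size from the gene universe, with
`p = (1 + #(null >= observed)) / (1 + nPerm)`. A correlation test is not a
defined construction for a set-overlap comparison, so the package uses this
explicit, calibratable permutation test; the universe is the full
annotation. Null calibration
(uniform p under random targets) is asserted in the acceptance suite by a
Kolmogorov–Smirnov bound at 500 repetitions.

# qPCR quantification

Expression: `0.5^Ct(gene) / 0.5^Ct(reference)` = `2^(Ct(ref) - Ct(gene))`;
ChIP enrichment: `0.5^Ct(IP) / 0.5^Ct(input)`. `foldChangeWithTest()`
aggregates replicate ratios (mean ± SEM with the sample, n-1, standard
deviation — the convention for n = 3 biological replicates) and applies a
two-sided **equal-variance** (Student) unpaired t-test, significant at
p <= 0.05. Of the two common unpaired variants the equal-variance one is
used and recorded in the output (`variant = "student"`). Input
normalization happens per replicate, then matched replicate ratios are
compared across conditions — normalize first, divide second is this
package's convention. Constant equal
groups degenerate to fold change 1, not significant.

# The synthetic-data generator

`generateDataset()` writes a complete toy experiment. It is a first-class,
tested module — it defines the conditions under which the pipeline's
recovery properties are demonstrated.

**Geometry.** Chromosomes `chrS1..chrSn` of equal (auto-sized) length.
Early summits sit on a jittered grid (spacing 3 kb ± 400 bp, so 200 bp
summit windows and ±1 kb track windows never overlap). A configured fraction
(`retentionRate = 0.60`) of early peaks — an exact count, not a Bernoulli
draw, since the rate *is* the condition being planted — is retained at the
late stage with identical summits (the same genomic element stays bound).
Late-only peaks are placed constructively: `fracLateOnlyWithin40kb = 0.58`
of them at 210 bp–40 kb from a random early summit (at least 210 bp from
every planted summit, so windows never collide and subtraction is exact),
the rest in desert zones more than 40 kb from any early peak. A 5% tranche
of sub-threshold peaks (FE uniform on [2, 9.9]) is added in a separate zone
so FE filtering and unfiltered-set subtraction are exercised end to end.

**Sequence.** Background is i.i.d. uniform A/C/G/T — the simplest null for
consensus scanning. Each 200 bp summit window is rejection-sampled until a
rescan reproduces its designated truth exactly: windows designated
motif-negative contain no spurious core-motif hit on either strand, and
embedded motifs are verified after insertion (junction-created hits cause a
resample). Ground truth and scan results therefore agree by construction,
which the tests assert. Default embedding rates are DECA 75% / HEXA 11% /
PBX:HOX 5% in early windows and 7% / 44% / 24% in late-only windows (HEXA
only ever in DECA-free windows, matching the exclusion-aware counting);
PBX:HOX centers are offset from the summit by a truncated normal
(mean 10 bp, sd 4), sliding outward if they would overlap another planted
motif; CCAAT is planted next to half the DECA sites (`nfyRate = 0.5`) at a
signed truncated-normal spacing (mean 20 bp, sd 5, minimum 8 bp so the sites
never overlap). The late-stage PBX:HOX rate is parameterized on the
late-only window set: retained late peaks reuse their early locus sequence,
so per-category rates are the generator's native dials.

**Chromatin and expression.** Each FE-filtered early peak gets a class label
at exact configured proportions (Class1..4 = 7/7/6/5%, non-MPAD 75%). Tracks
are Gaussian bumps (sd 150 bp) centered on summits with per-mark, per-class
amplitudes — H3K4me1 high for all MPAD classes and ~30-fold lower for
non-MPADs; H3K27ac(early) graded 10/5/1.5/0.3 across Classes 1–4 with
H3K27me3 high only in Class 4; H3K27ac(late) raised at Class 4 and lowered
at Class 1 so the stage transition has the right sign — plus additive
Gaussian noise (sd 0.2) floored at zero, emitted as 25 bp bedGraph runs.
Read-level simulation, mappability and GC structure are deliberately out of
scope: passing tests demonstrate recovery of planted structure under clean
signal, not robustness to alignment artifacts. One TSS per gene is placed
within 20 kb of a class-labeled peak (`genesPerClass = 120`); TPM replicates
are log-normal (sd 0.4 on the log scale) around class baselines
(100/60/20/5 TPM for Classes 1–4, 10 for non-MPAD), the knockdown condition
multiplies Class 4 gene means by 0.25, and the DE table is computed from the
true means (DE model fitting is out of scope). Ct tables encode the same
truths through the ΔCt formulas with ~0.1-cycle noise.

Peak-interval widths (~400 bp) are free parameters; they only affect
center-based gene association, and the defaults are documented in
`syntheticConfig()`.

**Determinism.** Everything derives from one integer seed through an
isolated RNG scope; identical configs give byte-identical files, recorded
with MD5 checksums in `manifest.json`.

# Problem sizes

The packaged test and acceptance runs use 5000 peaks per stage for motif
prevalence, 2000 for peak dynamics, 4000 for the chromatin classifier, 2000
windows for motif spacing, 500 repetitions for permutation-p calibration and
1000 simulations for the Kruskal–Wallis type-I check — sizes at which the
binomial sampling error of every recovered percentage is well inside a
±3-point band. Unit tests run the same operations at n of tens to hundreds
against brute-force oracles.

# Known limitations

* The motif model is consensus/regex, not PWM scoring; partially matching
  sites are invisible.
* The exclusion rule is sequence-scoped per 200 bp window; a DECA match at
  one window edge suppresses a HEXA call at the other edge.
* Chromatin classes come from k-means on raw signal; with fewer MPADs than
  `k`, class assignment degenerates (handled, but the labels are then
  trivial).
* `enrichmentVsRandom()` draws gene sets uniformly; it does not match
  covariates such as TSS density or expression level.
* The synthetic tracks are noise-floored Gaussian bumps; conclusions about
  real ChIP-seq backgrounds, replicate structure or peak-calling artifacts
  are outside what the round-trip tests establish.
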