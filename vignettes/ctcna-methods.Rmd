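---
title: "Models and methods behind ctcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ctcna analyses copy-number aberrations (CNAs) in single circulating tumor
cells (CTCs) profiled by low-pass whole-genome sequencing after single-cell
whole-genome amplification (WGA). This vignette explains the models the
package implements, the defaults it chooses where a choice had to be made,
and what its synthetic-data tests do and do not demonstrate about real data.

## The count model and the synthetic cohort

Everything downstream works on read counts in fixed-size genome windows
(bins). The simulator draws the count of bin $i$ from a negative binomial,

$$X_i \sim \mathrm{NB}\!\left(\mu_i = d \cdot \frac{c_i}{2} \cdot b_i,\;
\mathrm{Var} = \mu_i + \phi\,\mu_i^2\right),$$

where $d$ is the expected depth per bin at copy number 2 (default 100),
$c_i$ the ground-truth integer copy number covering the bin midpoint (2
outside truth CNAs), $\phi$ the dispersion (default 0.05, i.e. a
coefficient of variation near 25% at depth 100 — typical of WGA low-pass
libraries), and $b_i$ a multiplicative bias term. Two WGA artifacts are
modelled on top:

* **Random dropout.** With probability `dropout_rate` (default 0.02) a
  bin's count is shrunk by a uniform factor in $[0, 0.5)$, mimicking
  stochastic locus under-amplification.
* **Recurrent bias loci.** A small set of intervals
  (`n_artifact_loci = 3` loci of `artifact_bins = 12` bins, over-amplified
  by `artifact_multiplier = 1.7`) is drawn once per cohort and applied to
  *every* cell, CTCs and leukocytes alike. Single-cell WGA chemistry
  over-amplifies specific loci reproducibly, which is why leukocyte
  profiles from such workflows are near- but not exactly diploid. These
  shared artifact calls are also what gives the Jaccard index (below) its
  graded behaviour: without any shared aberration content, every aberrant
  CTC would score exactly 0 against every leukocyte regardless of how
  aberrant it is. At the default grid the artifact footprint is 1.5% of
  bins, inside the package's own leukocyte-specificity bound (at most 2%
  of bins called aberrant in at least 95% of simulated leukocytes).

Ground-truth CNAs for a CTC are sampled as a mixture of arm-scale events
(half a chromosome, probability `arm_prob = 0.5`) and focal events
(log-normal length, 10–80 bins), with copy states drawn from
`cn_weights` (defaults 3 and 4 for gains, 1 and 0 for losses, gain-heavy
as chromosomally unstable gut adenocarcinomas are), until a target
aberrant genome fraction is covered. The defaults encode the study
conditions the package is built around: relapsed-patient CTCs at fraction
0.4 versus disease-free at 0.1, attenuated by 0.6 at the post-neoadjuvant
time point to mimic therapy-induced reduction of genomic imbalance, in an
11-patient cohort whose per-stratum CTC counts are 20/27/10 across time
points A/B/C and 15+5, 13+14, 1+9 across relapsed/disease-free. The paper
trail behind the package states only those stratum totals; the split
across individual patients in `default_patients()` is a fixed design
choice. One caveat follows from the composition: time-point margins mix
the outcome groups (time point A is relapsed-heavy, C disease-free-heavy),
so marginal A-vs-C contrasts partly reflect outcome composition rather
than a time effect.

The default genome is a desk-scale toy (8 chromosomes, 240 Mb, 2,400 bins
of 100 kb) so that a full cohort simulates and calls in seconds; any
genome table can be supplied instead. Repeated-run tests (20 cohort
replicates) use 200 kb bins; single-run tests use the 100 kb default.
All randomness flows from one explicit seed per call; identical seeds
give byte-identical cohorts.

What the simulator does *not* emulate: GC-content waves (an optional
per-bin `gc` field and loess-based correction exist, but the generator
never produces GC bias), mappability gaps, replication-timing structure,
breakpoint micro-homology, or subclonal (non-integer) states. Green tests
therefore certify the pipeline's statistical logic and its behaviour under
WGA-like overdispersion — not performance on any particular real library.

## CNA calling

Per cell, counts are divided by their median over valid bins, anchoring
the genome-wide median at ratio 1. Segmentation operates on
$\log_2(\text{ratio} + 10^{-6})$ (the $\epsilon$ admits zero ratios in
homozygous deletions) per chromosome:

1. **Outlier smoothing.** Isolated spikes (dropout bins) are pulled to a
   running median (window 7) when they deviate by more than 3 robust
   standard deviations, the conventional pre-smoothing of read-depth
   segmenters.
2. **Change-point detection.** Penalized least squares solved exactly by
   optimal partitioning (dynamic programming over all admissible previous
   change points), with a minimum segment length of `min_bins = 5` and a
   BIC-style penalty $2\hat\sigma^2\log n$ per change point, where
   $\hat\sigma$ comes from the median absolute successive difference
   (robust to the change points themselves). The log scale is close to
   variance-stabilizing for negative-binomial counts with constant
   dispersion, which is what makes a single global penalty workable.
3. **Ploidy-grid rescaling.** Median normalization anchors whatever state
   holds the genome-wide median at copy number 2, which is wrong for
   cells whose dominant aberrant state covers more than half the genome.
   A grid search over scale factors $s \in [0.5, 2]$ minimizes the
   bin-weighted squared distance of $2 s m_k$ (segment levels $m_k$) to
   the nearest integers, plus a small $0.05\,(\log_2 s)^2$ preference for
   the smallest adjustment; ties (a diploid genome fits perfectly at
   $s = 0.5, 1, 1.5, 2$) resolve to $s = 1$, and noise amplification makes
   larger factors strictly worse on noisy data. Segment boundaries are
   scale-invariant, so only levels are rescaled.
4. **Integer states and the dual filter.** Each segment gets
   $\max(0, \mathrm{round}(2\,m_k))$ with half-away-from-zero rounding
   (a median ratio of 1.25 becomes copy number 3). Every non-neutral
   segment is then tested against the cell's own copy-neutral bins with a
   two-sided Mann–Whitney U test and a two-sample Kolmogorov–Smirnov
   test; a CNA is reported only if *both* p-values fall below
   `alpha = 0.05`, with no multiple-testing correction across segments —
   the filter is deliberately the raw dual-test rule, and the number of
   segments tested is recorded per cell. Adjacent passing segments with
   equal copy number are merged. A wholly aberrant cell (no neutral
   segment) is tested against a unit-ratio reference sample and flagged.

The Mann–Whitney p-value is computed by complete enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments whenever both samples have at
most 8 values. This in-house enumeration exists because exact p-values
are needed *including tied data* (a segment identical to the neutral
sample must give exactly p = 1), a case `stats::wilcox.test` refuses to
compute exactly; on tie-free inputs the two agree to machine precision,
and `wilcox.test`'s tie-corrected normal approximation is used for larger
samples. Reference population choice — the same cell's neutral bins, not
other cells — keeps calling strictly per-sample.

Coordinates are 0-based half-open everywhere, including the BED exports.

## Jaccard genomic imbalance

A cell's aberration content is the set of bins whose midpoint lies inside
a significant CNA, tagged gain (copy number > 2) or loss (< 2). For a CTC
$A$ and a leukocyte $B$,

$$JI(A, B) = \frac{|A \cap B|}{|A \cup B|},$$

computed at bin resolution (the calling resolution). Two conventions are
fixed here:

* **Empty ∪ empty = 1.** Two fully diploid profiles have identical
  (empty) aberration content; this is forced by reading JI = 1 as
  "complete overlap with a normal diploid genome".
* **Direction.** The default `status` mode counts a shared aberrant bin
  regardless of gain/loss direction; a `signed` mode requiring matching
  direction is available.

Each CTC is scored against five leukocytes — patient-matched when the
patient has enough, otherwise the cohort pool (the matching policy is a
flag) — and summarized by the mean (median and an unaggregated
one-row-per-pair mode exist for sensitivity analysis; whether a published
violin shows one value per CTC or per CTC–leukocyte pair is generally
ambiguous, so both are provided).

Group comparisons apply the Kruskal–Wallis test when more than two groups
are present and the pairwise Mann–Whitney U test for every unordered pair
(exact enumeration when both groups have at most 8 cells), with medians
and IQRs reported alongside. Under the simulator's defaults the relapsed
group's median JI falls below the disease-free group's in every seeded
replicate, and summary JI decreases monotonically in the true aberrant
genome fraction (Spearman $\rho < -0.9$ across fractions 0–0.6).

## Focal recurrence

A CTC counts toward a focal region if at least one of its significant
CNAs overlaps the region by at least 1 bp (a configurable minimum-overlap
is available), at most once per region and stratum. By default the call's
direction must match the region's kind (gains for amplification regions,
losses for deletions) since amplified and deleted panels are tabulated
separately; `match_kind = FALSE` lifts this. Percentages are
$100\,k/n$ rounded half away from zero to one decimal — the convention
under which 8 of 29 cells prints as 27.6 — and a zero-sized stratum
reports NA, never 0. The package ships a synthetic focal panel with 23
amplification and 19 deletion entries on the toy genome (mirroring the
size of the published esophageal-cancer panel) plus a loader for
user-supplied lists on real genomes.

## Enrichment and the term network

Per cell, the genes overlapping any significant CNA (`any_overlap`
default; a `contained` mode honors strict containment, but bin-resolution
breakpoints make containment unstable) form the query. Each gene set gets
the hypergeometric upper tail

$$p = P[X \ge k], \qquad X \sim
\mathrm{Hypergeom}(N = |\text{universe}|, K = |\text{term}|,
n = |\text{query}|),$$

the one-sided Fisher-exact family that gene-list enrichment tools
default to. The universe is the supplied gene annotation (not the union
of the GMT) because only annotated genes can ever enter a query.
Benjamini–Hochberg adjustment is applied per cell and terms with adjusted
p ≤ 0.05 are retained. Enrichment is per cell first, aggregated second —
never pooled across cells.

The term network has one node per term enriched in at least one cell.
Nodes carry the contributing cells, the union of their overlap genes, and
the fraction of contributing cells per time point; both the gene count
and the cell count are exported, since either can drive node size in a
rendered figure (the plot default is cells). An undirected edge joins two
terms exactly when their gene sets share *strictly more than* 10 genes
(≥ 11 at the default threshold). Exports are GraphML plus node/edge TSVs.

## Pipeline orchestration

`pipeline_config()` validates every stage's parameters up front — a
missing gene-set file, for example, aborts naming the enrichment stage
before anything runs — and `run_pipeline()` chains
simulate → call → imbalance/statistics → recurrence →
enrichment/network, writing each stage's files and a manifest with the
seed, parameters and an md5 per file; identical configurations reproduce
identical hashes. A YAML mirror of the configuration
(`read_pipeline_config()`) supports file-driven runs. The package
deliberately exposes no shell entry point: it is an analysis library, and
the exported functions, this vignette and the acceptance script are its
interface.

## Known limitations

* The toy genome is two orders of magnitude smaller than a human
  reference; absolute JI magnitudes and enrichment p-values depend on bin
  counts and panel sizes and are not transferable to hg19-scale data,
  although every rule and statistic is.
* The caller assumes one dominant ploidy state per cell; the grid-search
  rescaling corrects median mis-anchoring but cannot resolve genuinely
  ambiguous profiles (e.g. a perfect genome doubling).
* JI behaviour against near-diploid references hinges on shared WGA
  artifact content; against ideal, artifact-free references the index
  degenerates to 0 for any aberrant cell.
* Raw-read simulation, alignment, GC-wave correction and allele-aware
  (BAF) calling are out of scope.
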