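---
title: "Triad expression remodeling and heterosis: models and design choices"
author: "triadex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triad expression remodeling and heterosis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadex)
```

This vignette documents the statistical models behind triadex, the parameters
that matter, the places where the design was genuinely open and how they were
decided, and what the synthetic-data validation does and does not establish.

## The triad model

A *triad* is a hybrid together with its two parents. For each gene we reduce
the triad to three pairwise relations — parent A vs parent B, F1 vs A, F1 vs
B — each taking one of three values (greater / less / not significant), giving
27 possible patterns. The relations come from the study-wide differential
expression rule: a comparison is called only when *p* < 0.05 **and**
|log2 fold change| strictly exceeds 1. "Equal to a parent" is operationalized
as a non-significant call; no equivalence test is attempted, mirroring the
threshold logic of the upstream literature.

### The 27-pattern map

The 14 subcategories are named in the source literature but the full
27-pattern mapping is not printed anywhere; the mapping adopted here is fixed
by three anchors: transgressive classes 1 and 6 arise from parents that do
*not* differ; additive classes 11/12 are strictly intermediate between
differing parents; dominance classes 4/5 and 9/10 have the hybrid equal to
exactly one (the higher / the lower) parent. The hyper side is 1–5, the hypo
side 6–10, and within each pair the index records which labeled parent is the
higher one. All 14 remaining patterns — for instance F1 above one parent and
below the other while the parents do not differ — are contradictory under any
of these readings and form class 14 ("other"). The map is total and
deterministic; an independently written brute-force oracle re-derives it in
the test suite.

Two exact symmetries are asserted as properties:

* *parent relabeling* (swap A and B) permutes 2↔3, 4↔5, 7↔8, 9↔10, 11↔12 and
  fixes 1, 6, 13, 14;
* *mid-parent mirroring* (reflect expression about the mid-parent, keeping
  the labels) permutes 1↔6, 2↔7, 3↔8, 4↔9, 5↔10. These five pairs are exactly
  the "contrasting pattern" pairs used later when methylation remodeling is
  matched against expression remodeling.

### Parent orientation

A subtle but consequential choice: against *which* ordered parent pair is a
hybrid classified? Classifying each hybrid against its own
(maternal, paternal) order makes subcategory labels of reciprocal hybrids
incomparable — the same expression state would receive swapped labels, and a
gene could never be, say, "class 4 in both F12 and F21", because the two
orientations contradict each other on the parental relation. triadex
therefore assigns each crossing combination one canonical parent order (the
first-declared hybrid's maternal, paternal pair, e.g. (P1, P2) for F12/F21)
and classifies both reciprocal hybrids against it. The orientation is
recorded in every assignment. Reciprocal-consistent genes (ReCGs) are then
simply genes with the identical subcategory in both reciprocal hybrids;
doubly conserved genes are excluded, since ReCGs are meant to capture
consistency of *remodeling*. Whether ReCG should instead demand only the same
major category is not decidable from the available description; strict
subcategory equality was chosen and is switchable by comparing `major`
columns directly.

## The differential-expression test

The upstream study ran DESeq2; triadex substitutes a documented internal
test so that the pipeline is self-contained and its operating
characteristics are checkable:

* default `welch_log`: a two-sided Welch t-test on log2(FPKM + 1) replicate
  values. The reported fold change is computed on replicate-mean FPKM with a
  pseudocount of 1, so a true two-fold change sits exactly on the |log2FC| = 1
  boundary and is *not* called (the inequality is strict).
* `nb_wald`: a per-gene negative-binomial GLM on raw counts with a
  library-size offset (MASS::glm.nb, quasi-Poisson fallback), for users who
  carry counts.
* `lfc`: deterministic fold-change-only calls on genotype means, used for
  noise-free matrices where replicate variance is zero by construction.

Degenerate inputs are handled explicitly rather than by adding artificial
variance: when both groups are constant with equal means, p = 1; when both
are constant but different, the test falls back to an exact permutation of
replicate labels (with 3 + 3 replicates the smallest attainable p is 0.1, so
such genes are never called — a deliberate conservatism). Raw p-values are
used for DE calls, matching the source convention; BH adjustment
(`bh_adjust`, a validated wrapper over `stats::p.adjust`) is applied at the
enrichment stage only. No fold-change shrinkage is applied anywhere; this is
a documented deviation from DESeq2 behavior.

Calibration is a tested property, not an assumption: on a null
negative-binomial simulation (equal means, 3 vs 3, 2,000 genes, dispersion
0.05) the fraction of p < 0.05 must lie in [0.03, 0.07], and power must rise
monotonically over planted effects of 1, 2, 3 log2 units.

The low-expression filter retains a gene if *any* genotype's replicate-mean
FPKM reaches 1 — the literal reading of "discarded if below 1 in all seven
genotypes" — which keeps the maximal gene universe.

## Inheritance sets and the DIG rule

The set ledger is pure set algebra over DE calls, with two choices worth
recording. First, overlap percentages are asymmetric: 100 × |A∩B| / |A| with
the first-named set as denominator, which is how ranges like "the overlap
between HEGs and PEGs" are naturally phrased per comparison. Second, the
differentially-inherited-gene rule is nowhere formalized upstream; the
operational definition used here is the minimal one that makes "the hybrids
selected different expression levels from their parents" testable: a DIG
(i) is DE between the two hybrids, (ii) each hybrid is non-significant versus
*exactly one* of its own parents, and (iii) the matched parents differ. The
matched parent is the hybrid's inheritance origin, from which maternal
attribution is computed. Admitting genes where a hybrid is ns versus both
parents was considered and excluded (condition ii); relaxing it is a
one-line change in `detect_digs`. DIGs ⊆ HEGs holds by construction and is
asserted on every run.

## Heterosis indices

MPH and BPH are percent deviations of the hybrid genotype mean from the
mid-parent and from the optimal parent. "Optimal" defaults to the larger
mean — all bundled traits are larger-is-better — with a per-trait override
for traits where smaller is better. Indices are computed on genotype means
over replicates, not on per-replicate pairings. Both indices are
scale-invariant, and BPH ≤ MPH holds algebraically for positive traits with
distinct parents; both facts are asserted exactly. The one-way ANOVA guards
its degenerate corners explicitly (all-constant equal groups give p = 1;
constant unequal groups give p = 0 flagged as degenerate) and otherwise
defers to `lm`/`anova`.

## Enrichment and the hub screen

Term enrichment is the upper-tail hypergeometric test with BH correction over
the tested terms; a term passes only with padj < 0.05 *and* at least 5 study
genes. The background is the filtered gene universe — the set of genes that
could have been called — which is standard practice where the upstream
description is silent. The term map is taken as already propagated; no
ontology-graph traversal is performed.

The hub screen's published ratio criteria, |E_F12/E_F21| < 1 and
|E_C1/E_C2| > 1, cannot be literal: an absolute raw ratio below 1 just means
"smaller", and the second criterion would be satisfied by almost every gene.
Both are therefore read as bounds on the |log2 ratio| — balanced within the
reciprocal pair, contrasted between the crossing combinations — which is
symmetric in direction and treats the two criteria consistently. A
`ratio_mode = "literal"` switch preserves the raw reading for comparison.
Ratios use genotype means (per-replicate medians were considered and
rejected for symmetry with every other mean-based criterion).

## The methylation link

Methylation sites (CCGG / CCWGG restriction contexts, per-genotype RPM) are
assigned strand-awarely to gene bodies and 2 kb flanks (windows clipped at
position 1; no clipping against neighboring genes), and region levels are the
*sum* of site RPM — an "amount" — with mean-per-site as an option; the "all"
context is the sum of the two real contexts, an exact identity under sum
aggregation. Correlation with expression is computed across genes between
genotype-mean expression and genotype-mean region level, for all nine
region × context combinations.

Differentially methylated sites are classified with the *same* pattern map as
expression (shared code path, asserted identical on all 27 patterns), with
majors renamed OMS/BMS/AMS. Because genotype-level RPM carries no replicates,
the default calls are fold-change calls with a zero pseudocount (RPM is
strictly positive in this data type); externally computed differential
methylation calls can be supplied instead, which is the faithful mode when
prior studies provide them.

Gene-level concordance uses "any site" semantics: a gene × hybrid × context
is "consistent" if any of its sites shares the gene's expression subcategory
and "conflicting" if any site carries the mid-parent dual (1↔6, …, 5↔10);
a multi-site gene can carry both labels, and both are reported. Site-status
consistency within a gene is deliberately not required — matching is at the
level of the gene's remodeling pattern.

## The synthetic study

The generator emulates the study design: 7 genotypes (3 parents, 4 reciprocal
hybrids in 2 crossing combinations) × 3 replicates, ~55% conserved genes with
the remainder spread symmetrically over the remodeling classes, planted
|log2FC| of 2 between "different" triad levels, negative-binomial counts at
dispersion 0.05, log-uniform FPKM base means (32–512) and gene lengths
(0.5–5 kb), nominal depth 5 × 10^6 reads. Each gene's subcategory is realized
*exactly* in its noise-free genotype means; a generation-time check
classifies the mean matrix and aborts on any mismatch, so "100% noise-free
recovery" is a verified contract, not a hope. A reciprocal hybrid repeats its
partner's level with probability 0.5 and otherwise draws a feasible
alternative class given the fixed parent levels — this is what plants DIGs
and reciprocal inconsistencies. Class-14 genes are built with sub-threshold
parent gaps (0.9 on the log2 scale) and a mixed F1 offset (1.45), the one
construction that forces a contradictory pattern at the default thresholds.

Two numerical consequences of FPKM being a *relative* measure deserve
emphasis. First, since the sum of FPKM × length over genes is fixed by
definition, the planted matrix is rescaled once so the floor of the base-mean
range survives the classifier's pseudocount shrinkage; the generator verifies
this and rejects configurations whose floor falls too low. Second, total-count
library scaling is dominated by the planted differential tail — hybrids
carrying transgressive-up patterns inflate their own libraries by tens of
percent, shifting every gene's apparent cross-genotype ratio. Realized FPKM
therefore uses median-of-ratios size factors (the median gene is conserved),
the same normalization idea the study's own DESeq2 stage relies on. With
total-count scaling, planted-class recovery fluctuated between 82% and 91%
across seeds; with size factors it is stable near 96%.

Methylation coupling is planted per (region, context): a latent score
ρ·z + √(1−ρ²)·ε (z = standardized expression) maps linearly to the region
aggregate, so the across-gene Pearson correlation equals ρ up to sampling
noise; the aggregate is split over sites by symmetric Dirichlet weights, and
each site carries its own planted remodeling pattern with per-genotype
multipliers normalized to preserve the aggregate. The default signs follow
the gene-body-positive / upstream-inverted / downstream-negative structure
with CCGG dominant (slopes 6 vs 1.5), so the induced "all"-context sign is
determinate for every region. Where the narrative reports *no* relation
(upstream total, downstream CCWGG), the defaults still plant a small
coupling (|ρ| = 0.3 versus 0.5 elsewhere) so that sign recovery is a defined
check for all nine combinations; users can set those ρ to 0 to reproduce the
null narrative. Phenotypes plant MPH exactly at the population level
(hybrid mean = mid-parent × (1 + MPH/100)) with Gaussian replicate noise at
CV 0.05; the bundled defaults make the P1×P2 combination the strong cross
(MPH 30/25%) and P1×P3 the weak one (8/5%).

What the simulator does *not* emulate: transcript-length biases and GC
effects, batch structure, outlier replicates, correlated genes, ontology DAG
structure (the term map is flat and partly random), bisulfite-resolution
methylation or replicate-level RPM, and any linkage between seed traits and
seedling traits. Passing the validation therefore shows that the algorithms
implement their definitions correctly and behave as designed under idealized
NB noise — not that the thresholds are optimal for any particular real
dataset.

## Problem sizes and runtimes

The test suite validates at the scales the properties demand: 5,000 genes ×
3 replicates for noisy recovery (≥ 70% subcategory, ≥ 85% major category —
both comfortably exceeded at ~96%), 2,000 genes for DE calibration and for
methylation sign recovery, exhaustive enumeration for the classifier (27
patterns) and the hypergeometric oracle (all backgrounds up to 30 genes).
The full pipeline on the bundled 2,000-gene configuration runs in well under
a minute on one CPU and is byte-identical across reruns with the same seed.

## Known limitations

* The 27→14 mapping is this package's reconstruction; other groups'
  "fourteen categories" may differ in how classes 11/12 and the
  contradictory remainder are delimited. The mapping is a single table
  (`class_from_pattern`) and easy to swap.
* With 3 + 3 replicates the Welch test cannot call constant-but-different
  genes (permutation floor p = 0.1); genuinely noise-free real data would
  need more replicates or the count-based test.
* Genotype-level methylation RPM admits no within-genotype variance, so DMS
  calls from it are threshold calls, not tests; supply external differential
  methylation calls where available.
* FPKM-based inference inherits compositional caveats; the simulator controls
  them by design, real data may not.
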