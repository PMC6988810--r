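---
title: "Methods: two-habitat protist community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-habitat protist community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

protistnet implements the downstream statistics used to compare the
planktonic protist communities of two connected habitats from an 18S
V4 metabarcoding OTU table. This vignette records the models and the
design choices behind each stage; the README shows the user-facing
workflow.

## Input model and normalization

The central object is an integer OTU-by-sample count matrix with
unique row and column ids, validated on construction (negative,
non-integral or non-finite cells are hard errors naming the offending
cell). Sample metadata binds each sample to a station, one of exactly
two habitats, a date, and a replicate number.

Replicate filters from the same station and date are pooled by
summation before any normalization: duplicates are technical
replicates of one water mass, and pooling them stabilizes per-sample
depth without averaging away real variation. Singleton OTUs (total
count 1 across the whole table) are removed, the standard guard
against sequencing-error OTUs; the filter is idempotent and order
preserving.

Rarefying draws, for each sample, a subsample of fixed depth without
replacement — a multivariate hypergeometric draw, delegated to
`vegan::rrarefy()` — so that every retained column sums exactly to
the target depth. The default depth policy is the *second-lowest*
column total: surveys often contain one sample that failed partially,
and this policy drops exactly that sample (with a warning) while
keeping the depth as high as possible. A fixed-depth and a
lowest-total policy are available; with-replacement (multinomial)
resampling exists behind a flag but is off by default because it
inflates the variance of rare-OTU counts. Every randomized stage
takes an explicit seed; the pipeline derives per-stage seeds from one
master seed with a fixed integer mix, so one integer reproduces the
whole analysis.

Diversity statistics follow the conventional definitions: Shannon
*H* in natural log units (on tables with thousands of OTUs the nat
scale is what values like *H* ≈ 3.7–4.1 imply); rarefaction curves
use the exact hypergeometric expectation
*E[S(d)] = Σᵢ (1 − C(N−Nᵢ, d)/C(N, d))* rather than resampling, for
determinism — a resampling mode exists purely as a cross-check and is
exercised in the tests. Bray–Curtis and the Hellinger transform are
thin wrappers over vegan with the package's error contracts
(all-zero columns are errors, not NaNs). Ordination itself (nMDS,
CCA, PERMANOVA) is deliberately out of scope: those are standard
package methods, and this package only prepares their inputs.

## CLAM habitat classification

To score habitat affinity, counts are pooled per habitat (optionally
over a station subset chosen to balance the two environments) and the
deeper pool is subsampled to the shallower one, so the two totals are
equal. For an OTU with equalized counts *(a, b)* the model conditions
on *t = a + b* and treats *a* as Binomial(*t*, π), where π is the
OTU's preference for habitat A. Two-sided 1 − 2α confidence bounds on
π give the call, with the supermajority threshold *K*:

- specialist of A if the lower bound is strictly above *K*;
- specialist of B if the upper bound is strictly below 1 − *K*;
- generalist if the interval lies inside [1 − *K*, *K*] (bounds
  inclusive);
- otherwise too rare to classify. OTUs with *t* = 0 are reported
  too-rare rather than dropped.

Defaults are *K* = 2/3 and α = 0.005 per side, the conservative
convention for this test. The published implementations of the test
do not pin down one interval construction, so the package defaults to
exact Clopper–Pearson bounds — conservative, assumption-light, and
available in closed form via the beta quantile — and offers a
normal approximation to the log Poisson ratio (`poisson_normal`) as a
cross-check; the two modes agree on essentially all high-count OTUs
and are compared in the tests rather than silently merged. Ties at a
threshold resolve toward the less specific class (hence the strict
inequalities for specialists). No multiplicity correction is applied:
the classification is descriptive, and α is already strict.
`clam_min_abundance()` exposes the implied detectability boundary —
the smallest one-sided total that can escape the too-rare class
(14 reads at the defaults, as the tests verify by scanning).

## MIC association networks

The maximal information coefficient of a pair of vectors of length
*n* is the maximum over grid shapes (*k_x*, *k_y*), with
*k_x·k_y ≤ B(n)* and both at least 2, of the maximal mutual
information over axis partitions normalized by log₂ min(*k_x*,
*k_y*). The package implements the ApproxMaxMI heuristic in C++:

- the budget is *B(n) = max(4, ⌊n^b⌋)* with *b* = 0.6; the floor
  keeps the minimal 2×2 grid available at the smallest supported
  *n* (8);
- one axis is equipartitioned into rows as evenly as possible with
  tied values never split across rows;
- the other axis is optimized by dynamic programming over *clumps*
  (maximal runs of tied values), using the decomposition
  I = H(Q) + Σ_columns φ(column) so each DP cell is a table lookup
  on integer counts; when the number of clumps exceeds *c·k_x*
  (clumps factor *c* = 15) they are first merged into superclumps by
  the same equipartition rule;
- both orientations are computed and the maximum taken; constant
  input returns 0 by convention.

Because only ranks and tie patterns enter, MIC is invariant to
strictly monotone increasing transforms of either variable, which the
tests assert to 1e-12. For small *n* the dynamic program is checked
against exhaustive enumeration of every cut-point subset (an
independent oracle in plain R); at the 28-sample scale of a pooled
two-habitat survey the grid budget admits only 2×2, 2×3 and 3×2
grids, so the exhaustive reference is feasible there too and the two
agree to floating precision.

Significance uses an explicit permutation null: *p* = (1 + #{permuted
MIC ≥ observed})/(1 + N) with N = 1,000 permutations of one vector by
default. This replaces lookups in precomputed null tables — an
external artifact tied to particular *n* and parameter values — with
a null constructed from the data; the *p* < 0.01 retention rule is
kept. The permutation loop reuses the observed-statistic workspace,
so the all-pairs stage stays inside a few minutes for a few hundred
OTUs on one core. No multiple-testing correction is applied across
pairs, preserving the raw-threshold convention; a
`p_threshold = 1` setting returns every pair for diagnostics.

Edge signs come from the nonlinearity statistic MIC − r²: values
strictly above 0.5 mark strongly non-linear dependence and are
treated as negative connections, everything else as positive. The
reading of the sign rule is isolated in `edge_sign()` so it can be
swapped without touching the network stage. Note the consequence
that a clean *linear* anticorrelation has high r² and is therefore a
*positive* connection under this rule; only dependence that the
correlation coefficient misses is labelled negative.

Before network inference, OTUs with fewer than 50 total reads are
excluded ("less than" strictly: a total of exactly 50 is kept) —
low-count vectors cannot support stable grid statistics at these
sample counts.

## Network statistics and nulls

The network is the simple undirected graph on OTUs incident to at
least one significant edge. *C* is the mean local clustering
coefficient with nodes of degree < 2 contributing zero (the
NetworkAnalyzer convention), and *L* is the mean shortest-path length
over connected ordered pairs; because the observed graph need not be
connected, the number of excluded pairs is reported, and *L*
restricted to the largest component is returned alongside. Both are
verified against brute-force oracles (explicit neighbor-pair
counting; all-pairs BFS) on random graphs.

The random null defaults to uniform simple graphs with the same node
and edge counts (G(n, m)); a degree-preserving edge-swap null (10·|E|
successful swaps per replicate) is available. G(n, m) was chosen as
the default because the characteristic "much lower C, shorter L"
random baseline reported for networks of this kind matches the
G(n, m) signature; the tests confirm the mean null clustering matches
the Erdős–Rényi density 2m/(n(n−1)) within Monte-Carlo error. Hubs
are nodes with degree ≥ 20 by default (configurable; the desk-scale
validation network uses a threshold matched to its planted block
size), sorted by degree with ties broken by id. Edges are summarized
by the CLAM classes of their endpoints (A–A, B–B, A–B,
generalist-involving, other) with the negative fraction per category.

## Trophic annotation

Rules live in an editable TSV (`taxon, rank, category`); the shipped
defaults encode only the group-level conventions: Bacillariophyta and
Mamiellophyceae as the strict autotrophs; other chloroplast-bearing
groups (Cryptophyceae, Chrysophyceae, Dictyochophyceae,
Trebouxiophyceae, Chlorophyceae, Rhodophyta, ...) as mixotrophs;
ciliates and heterotrophic flagellate groups as heterotrophs;
Syndiniales, Labyrinthulea, Oomycota, Perkinsea and similar with the
parasites. Dinophyceae deliberately have *no* group-level rule:
dinoflagellates span autotrophy, mixotrophy and heterotrophy, so
unnamed or unresolved dinophycean OTUs stay NA unless a
species/genus/family rule resolves them. Matching is by rank with
species > genus > family > group precedence; rule order never
matters, and two rules for the same taxon at the same rank with
different categories fail validation loudly. Composition summaries
report read fractions per category (NA included) within each
habitat-by-date group, summing to 1 per group.

## The synthetic generator

`generate_dataset()` emulates the sampling design of a two-habitat
coastal survey: 4 + 3 stations, 4 dates, 2 replicate filters → 56
samples. Expected relative abundances are built multiplicatively:

- lognormal(0, σ) base abundances (σ = 2 by default) reproduce the
  dominance structure in which a few taxa carry most reads and a long
  rare tail carries the diversity; a configurable fraction of OTUs is
  additionally shrunk into that rare tail;
- habitat preference: a specialist's expected abundance in its
  preferred habitat is `habitat_effect` (default 8) times its
  abundance in the other;
- seasonality: each OTU has one preferred date on which its weight is
  multiplied by `season_effect` (default 3), creating temporal
  turnover that the network stage must not mistake for habitat
  structure;
- association blocks: members share a latent per-event
  (station-by-date) lognormal factor with correlation share ρ,
  planting co-occurrence that survives replicate pooling.

Counts are then a multinomial draw per sample with lognormal library
sizes (mean 8,000 reads by default). There is deliberately no extra
per-cell overdispersion: under `habitat_effect = 1` the pooled
habitat counts stay near-conditionally-binomial, which is what makes
the type-I property of the classifier well defined and testable. The
generator returns per-OTU truth (class, group, trophic category,
block id, and expected relative abundance per habitat pool) for
recovery scoring via `truth_confusion()`.

Desk-scale defaults (300 OTUs, depth 8,000) are an order of magnitude
below a real survey (thousands of OTUs, tens of thousands of reads
per sample); they were chosen once so that full-pipeline validation,
including 1,000 permutations for every OTU pair, completes in minutes
on one core. What the generator does *not* emulate: compositional
coupling beyond the multinomial, sequencing-error OTUs (beyond
singletons), taxon-specific abundance distributions, copy-number
variation of the 18S gene, or chimeras. Passing recovery tests
therefore show that the statistics detect the structure they model,
not that real communities satisfy that model.

## Validation design and problem sizes

The test suite checks every stage against an independent oracle or a
closed form: exhaustive MIC enumeration at *n* ≤ 12 (200 cases) and
*n* = 28 (100 pairs, agreement within 0.02 where floating agreement
is exact in practice); permutation-null calibration over 500
independent pairs at 1,000 permutations (empirical rate of
*p* < 0.01 within 3 binomial SEs of 0.01); Clopper–Pearson bounds
against `stats::binom.test`; an exhaustive habitat-swap and
monotonicity scan over all count pairs with total ≤ 200; classifier
type-I on 200 null replicates of 500 OTUs and recall ≥ 0.9 of planted
strong specialists; graph statistics against brute-force oracles on
100 random graphs and the G(n, m) clustering expectation at
n = 100, m = 500; rarefaction against Monte-Carlo subsampling;
end-to-end recovery of two planted 14-member habitat blocks
(within-block > cross-block edges, hub enrichment for block members,
within-habitat > cross-habitat edge counts); and byte-identical
reruns of the whole pipeline under one master seed.

The network-recovery benchmark uses a tighter generator setting
(σ = 1.5, season effect 2, block correlation 0.98, block factor
σ = 1.2, hub threshold matched to the block size of 14): blocks must
dominate the habitat- and season-driven background dependence for hub
enrichment to be a meaningful planted signal, and these settings keep
all three recovery properties stable across generator seeds rather
than holding at a lucky one.

## Interfaces

The package is function-first: `run_pipeline()` plus the per-stage
functions are the API, and `scripts/acceptance.R` is the only shell
entry point (it reruns the default synthetic survey end to end and
writes the headline numbers as JSON). Outputs are plain formats
throughout — TSV tables, JSON summaries, GraphML for the network — so
downstream visualization (Cytoscape, Gephi) needs no special
importer. Layout algorithms, community detection beyond the
habitat-class edge summary, compositionality-aware association
methods (SparCC and relatives), and the remaining MINE statistics are
out of scope by design: the package reproduces this analysis
procedure faithfully rather than improving on it.

## Known limitations

- MIC p-values are permutation-based and therefore bounded below by
  1/(1 + N); with the default N = 1,000 the smallest attainable p is
  ~0.001. Raising the retention threshold's strictness below that
  requires more permutations.
- The sign rule inherits the quirks of the nonlinearity statistic
  (see above); it is a convention, not an inference.
- Rarefying discards data; the depth policy and seed are recorded in
  the manifest so the loss is at least reproducible.
- The CLAM conditional-binomial model ignores residual
  overdispersion between pooled samples; with strong within-habitat
  heterogeneity its intervals are anti-conservative in principle,
  which is one reason the strict α = 0.005 default is kept.
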