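---
title: "Methods: binned likelihood-ratio integration for PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned likelihood-ratio integration for PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppilr)
```

# The model

`ppilr` scores a candidate protein pair (A, B) by combining independent
evidence channels under a naive-Bayes assumption. For each channel X the raw
score domain is partitioned into bins $b_1,\dots,b_n$; the likelihood ratio
of a bin is the fraction of positive reference pairs falling in it divided
by the fraction of negative reference pairs,

$$LR^X_b = \frac{(pos_b + k)/(n_{pos} + Bk)}{(neg_b + k)/(n_{neg} + Bk)},$$

with $B$ bins and a per-bin pseudo-count $k$ (default 0.5) that prevents
infinite or zero ratios in sparse bins; $k = 0$ recovers the pure percentage
ratio, under which $\sum_b P(b\mid neg)\,LR_b = 1$ exactly (a property the
test suite asserts for every trained channel). The channel LRs multiply
into

$$LR = \max(LR^{SM}, LR^{PrP}) \cdot LR^{PR} \cdot LR^{GO} \cdot LR^{PP}
       \cdot LR^{OR} \cdot LR^{EP}.$$

SM (structural modeling) and PrP (protein–peptide) describe mutually
exclusive interaction geometries — two structured domains versus a domain
binding a peptide — so only the stronger of the two enters the product. The
printed form of this combination rule repeats the PR factor; we apply PR
once, because the structural score is consistently described elsewhere as
$\max(LR^{SM}, LR^{PrP})\cdot LR^{PR}$ and a silent squaring would double
the weight of one channel. A `square_pr = TRUE` switch exposes the literal
reading.

**Missing evidence** contributes a neutral factor of 1. Genome-scale
evidence coverage is heterogeneous by construction (structures exist for a
minority of proteins, expression data for most), and treating absence as a
zero-filled score would conflate "no data" with "contradicting data".

**Reliability.** A prediction is reliable when $LR > 600$ (strict
inequality, configurable). At this cutoff essentially no random reference
pairs are recovered, which the synthetic-world acceptance test reproduces
(< 2% random-pair recovery against materially higher planted-positive
recovery).

## Binning of continuous channels

The published bin boundaries for the supplied continuous channels (SM, PrP,
GO, PP, EP) are not available, so `train_models()` uses equal-frequency
quantile bins (default 10) estimated from the pooled training scores, with
outer edges widened to $\pm\infty$. Equal-frequency bins keep per-bin
training support balanced, which matters more for LR stability than the
exact boundary placement; the bin count is configurable.

# Evidence channels computed by the package

## Orthology (OR)

For a pair (A, B), each of four orthology source groups — `gopher`, `oma`,
`kegg`, and the pooled `union_group` of the remaining databases — reports
the number of distinct species in which some ortholog of A interacts with
some ortholog of B in cross-species experimental data. A species counts
once per source regardless of how many ortholog pairs interact in it.
Counts are encoded 0 / 1 / ">1" (stored as 2), giving a four-component
vector with $3^4 = 81$ possible bins — too many for the training data to
populate, hence **dimensional backoff**: the four-dimensional model is
consulted first, and if the vector's bin holds fewer than `min_support`
training pairs (default 10; the source material says only "sufficient
data") the search falls back through all three-source subsets, then two-,
then one-source subsets, in fixed lexicographic order over the source list
(`orthology_backoff_order()`). The order among same-dimension subsets is
unspecified upstream; a fixed deterministic order was chosen so scoring is
reproducible. If no bin is supported at any dimension, the evidence is
neutral (LR 1). Note the all-zero vector is itself an informative bin:
absence of orthologous interactions typically yields LR < 1.

## Partner redundancy (PR)

If proteins structurally similar to A are already known to interact with B,
an A–B interaction becomes more likely. The first network bins the pair
$(n, d)$ — $n$ = structural neighbors of A known to interact with B in the
within-species experimental set, $d$ = B's total partner count there — into
the cross product of $n \in \{0\},\{1\},[2,5],[6,\infty)$ and
$d \in [0,100],(100,\infty)$. Only the $([2,5],[0,100])$ cell is fixed by
convention; the remaining edges are package defaults chosen to bracket it,
and are configurable. The second, weaker but broader network bins $m$ — the
number of neighbor-of-A / neighbor-of-B pairs interacting in data from any
species — into $\{0\},\{1\},[2,5],[6,20],[21,\infty)$. Both A and B are
excluded from the neighbor sets before counting. The LR is taken from the
first network when its bin has at least `min_support` training pairs, else
from the second (which presumes a structure or model of B exists, so that
B's neighborhood is defined), else it is neutral.

The $(n, d)$ features are asymmetric in the pair orientation while the
combined score must be symmetric in A and B. The scoring pipeline therefore
evaluates both orientations and keeps the larger LR — evidence from either
direction counts, and the choice is deterministic.

## Cross-species expression (EP)

Pre-computed pairwise Pearson correlations are taken per expression dataset:
several human datasets, and one per non-human model species (correlations
between the pair's orthologs there). Per side, coefficients are aggregated
by sign: $S_{pos} = 1 - \prod_j (1 - c_j)$ over positive coefficients,
$S_{neg} = -(1 - \prod_j (1 - |c_j|))$ over negative ones, and the majority
sign wins (ties go positive). The displayed negative-side formula is
implemented with $|c_j|$; the literal $(1 - c_j)$ with negative $c_j$ would
leave the unit interval. Coefficients exactly 0 carry no sign information
and are dropped. The two sides combine as

$$COXS = \begin{cases}
1 - (1 - S_{human})(1 - S_{orth} w) & S_{human} \ge 0, S_{orth} \ge 0\\
S_{human} & S_{human} \ge 0 > S_{orth}\\
S_{orth} & S_{orth} \ge 0 > S_{human}\\
-(1 - (1 - |S_{human}|)(1 - |S_{orth}| w)) & \text{both} < 0
\end{cases}$$

with damping weight $w = 0.6$ on the ortholog side (the value reported to
maximize positive-set recovery). When only one side has data, that side's
aggregate is used directly — the four-branch rule needs both, and a
passthrough preserves coverage without inventing a second weight. With no
data at all the channel is absent.

# Evaluation machinery

*ROC.* $TPR = |\{pos : LR > t\}|/n_{pos}$ and $FPR$ analogously over every
distinct threshold; unscored reference pairs count at the neutral LR 1. The
trapezoidal area under the full step curve equals the rank statistic
(probability a random positive outscores a random negative, ties at half),
which the tests verify against explicit enumeration.

*Compartment-crossed negatives.* Evaluation negatives are built by sampling
per-compartment protein quotas (seeded) and emitting all cross-compartment
pairs under a fixed pairing rule list; proteins annotated to more than one
quota compartment, or explicitly excluded (e.g. positive-set proteins),
never appear.

*Complex recovery.* A complex's recovery LR is the largest cutoff at which
its members still form a connected graph, i.e. the bottleneck of a maximum
spanning tree of the member-induced weighted graph (computed via igraph's
MST on negated weights; the test oracle sweeps thresholds with a hand-rolled
BFS). Member pairs without a score get weight 0 — not "absent" — so
disconnection is well defined. The null control replaces each complex with
a size-matched uniform sample of proteins. Curve thresholds default to the
distinct recovery LRs plus the canonical 600 gridpoint.

*Seeded member prediction.* Candidates are all proteins scoring above the
reliability threshold against either seed member, ranked by the larger of
the two seed LRs with lexicographic tie-breaks. The upstream ranking rule
("top 10 partners") is unstated; max-over-seeds was chosen as the natural
extension of per-seed partner lists and is deterministic.

# Function annotation (preranked GSEA)

A query's interactors are ranked by descending LR (ties lexicographic;
unscored proteins appended at LR 1, query excluded). For a gene set, the
running sum adds the item weight (normalized by total hit weight) at hits
and subtracts $1/(N - N_{hits})$ at misses; the enrichment score is the
maximum signed deviation. Item weights default to $\log_{10}(\max(LR, 1))$:
raw LRs span many orders of magnitude and a single $10^6$ pair would
otherwise dominate the walk ("raw" and rank-only modes are provided). When
every hit weight is zero — all ties at LR 1 — hits fall back to equal
weights so the statistic stays defined.

Nominal p-values come from gene-label permutations (default 1000, seeded):
each permutation reassigns which ranked positions are hits, shared across
sets within an iteration. q-values are Benjamini–Hochberg across the tested
sets, and sets with $q < 0.01$ are flagged enriched; the upstream
software's internal FDR is not reproduced bit-for-bit. Note an arithmetic
consequence: with $S$ sets, the smallest attainable q is
$\frac{1}{n_{perm}+1} S$, so clearing $q < 0.01$ requires
$n_{perm} \gtrsim 100\,S$. One exact invariance that does *not* hold:
appending zero-weight tail items changes the miss step $1/(N - N_{hits})$
and thus perturbs the ES by up to $k/(N + k - N_{hits})$ for $k$ appended
items; the tests assert this bound rather than exact invariance.

# Variant–interface enrichment

Every residue of every variant-bearing protein is classified interfacial ×
mutated, giving counts $(n_{11}, n_{10}, n_{01}, n_{00})$. The odds ratio
is the cross-product ratio $OR = n_{11} n_{00} / (n_{10} n_{01})$: the
upstream prose defines $p_2$ as the interfacial fraction among *all*
residues, which does not reproduce the published values from the published
counts, while the cross-product ratio (equivalently, $p_2$ read as the
interfacial fraction among *unmutated* residues) does. The log-odds
standard error is $\sqrt{\sum 1/n_{ij}}$ and $Z = \ln(OR)/SE$. Direct
evaluation of these formulas on the published disease/benign tables gives
$|Z| = 45.4$ and $36.3$, whereas the source text prints "~41" and "~35";
the implementation matches the formulas, and the discrepancy is documented
rather than patched. An optional Haldane–Anscombe 0.5 pseudo-count handles
zero cells (off by default).

# The synthetic world

`generate_world()` emits a complete, seeded input bundle with the
statistical structure the pipeline assumes. Choices, with rationale:

* **Graph**: 2,000 proteins in 50 functional modules (block model),
  within-module edge probability 0.25 over a $5\times10^{-4}$ background —
  roughly 10,000 true edges, a density at which reference sets of realistic
  size (thousands of pairs) exist.
* **Continuous channels**: Gaussian emissions with unit sd and
  true-pair mean shifts of 2.0 (SM), 1.5 (PrP, GO), 1.0 (PP); coverages
  0.5/0.3/0.8/0.6 mirror the reality that structural evidence is scarcer
  than annotation-based evidence. Shifts of 1–2 sd give clearly separated
  but overlapping distributions — single channels are informative, none is
  an oracle.
* **Expression**: 3 human datasets plus 10 model species; true pairs draw
  $r \sim N(0.4, 0.25)$, non-pairs $N(0, 0.3)$, clipped to $(-0.99, 0.99)$;
  dataset coverage 0.6.
* **Orthology**: 5 species, 80% ortholog coverage, per-source map coverage
  0.7/0.6/0.5/0.8; a true pair's orthologs interact in a species where both
  are mapped with probability 0.35, plus 200 random noise interactions per
  species. Evidence flows through the same counting code the user-facing
  reader uses.
* **Partner redundancy**: structural neighborhoods are same-module samples
  (Poisson mean 4); the "known interaction" set is a 60% subsample of
  *training-side* true edges only, so partner-redundancy evidence never
  leaks test labels.
* **References**: true edges split 50/50 edge-disjoint into train/test;
  each side observed into an HC-style positive set with probability 0.7
  (the "two publications" filter). Training negatives are sampled
  non-edges; evaluation negatives are compartment-crossed pairs (quotas
  10%/2.5%/2.5%/1.9% of the proteome across four compartment labels, 5%
  dual-annotated proteins exercising the exclusion rule), minus any true
  edges.
* **Complexes and gene sets**: complexes are random 3–8-member subsets of
  modules; gene sets are module memberships with 10% dropout plus an equal
  number of size-matched random decoys.
* **Variants**: 300 proteins of 150 residues, 15% interfacial; each variant
  lands interfacially with the odds-$\theta$ tilt, $\theta = 1.6$ — the
  published disease-variant enrichment, making parameter recovery a direct
  check of the estimator.

`null_world_config()` defines the zero-signal control: identical emission
distributions for true and non-pairs (both mean *and* sd — an early version
left class-specific correlation sds, which is itself a planted signal), no
orthologous propagation, global neighborhoods, and random known-interaction
sets. Module labels persist, so evaluation machinery runs unchanged.

**What a green test establishes — and what it does not.** The synthetic
world has conditionally independent channels given the true label, which is
exactly the naive-Bayes assumption; real evidence sources are correlated
(e.g. GO similarity and expression), so the test-split AUC > 0.9 asserted by
the acceptance suite validates the machinery, not the calibration one would
observe on real proteomes. Similarly absent from the emulation: realistic
degree heterogeneity and study bias, sequence/structure realism, ontology
structure within gene sets, and linkage between compartments and modules.
Recovery *fractions* on synthetic data are not comparable to published
full-proteome figures (1.35 M predictions, 2/3 complex recovery, etc.),
which require the real structural corpus and reference databases; the
acceptance suite therefore substitutes oracle-equivalence, closed-form and
parameter-recovery checks, as specified.

# Numerical and interface conventions

* Pair keys are canonicalized by lexicographic ordering joined with `|`
  (ids must not contain that character); all scores are symmetric in A, B.
* Numeric bins are right-closed with a closed first interval; grid bins
  match the first containing range per dimension.
* The reliability comparison is strict (`> 600`), as are recovery
  thresholds; complex-recovery curves use `>=` on the recovery LR so a
  complex whose bottleneck equals the gridpoint counts as recovered there.
* All randomness (sampling, permutations, null complexes) flows through
  per-call seeds; library calls never disturb the caller's RNG state, and
  derived seeds stay below $2^{31}$.
* Tabular I/O is TSV with headers, empty cell = absent, floats at 6
  significant digits, LRs never clipped; gene sets use GMT; models
  round-trip through JSON.

# Known limitations

* The naive-Bayes product ignores inter-channel correlation; on real data
  the combined LR is therefore optimistic, which is why the reliability
  cutoff is calibrated against a negative control rather than read as a
  posterior odds.
* Quantile bin boundaries depend on the training pool; models must be
  serialized (not refit) to score new data consistently.
* The GSEA permutation null permutes gene labels, not sample phenotypes;
  with strongly correlated gene sets the BH q-values are conservative.
* `build_contingency` OR-reduces interface masks per protein; per-pair
  interface attribution is not retained.
* The CLI is a thin deterministic wrapper; it does not parallelize, and
  world directories are trusted (no schema versioning beyond the manifest).
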