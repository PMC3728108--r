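---
title: "Methods: detecting and analysing coevolving amino acid sites"
author: "CoevNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing coevolving amino acid sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Residues that are structurally or functionally linked exert reciprocal
selection on each other: a substitution at one site favours compensatory
substitutions at its partners. Across a deep phylogeny this leaves a
signature of *correlated evolutionary variation* between alignment columns.
CoevNet detects such pairs within one protein and between two interacting
proteins, assigns each pair a phylogenetic reliability, organises the
retained pairs into networks, and asks whether the coevolving groups found
in different clades behave as independent "sectors" on the protein
structure. The motivating system is the bacterial chaperonin pair
GroES–GroEL, but nothing in the code is specific to it.

# The covariation statistic and its null

For column $i$ and sequence pair $(s,t)$, both ungapped at $i$, the score is

$$x_i(s,t) = \frac{B(a_{is}, a_{it}) - \bar B_i}{t(s,t)},$$

with $B$ a BLOSUM62 transition score, $\bar B_i$ the mean of $B$ over the
pairs included at column $i$, and $t(s,t)$ the divergence time of the two
sequences. Sites $i,j$ are scored by the Pearson correlation $r_{ij}$ of
$x_i$ and $x_j$ over the jointly unmasked sequence pairs.

Assumptions worth keeping in mind:

* The divergence correction treats substitution weight per unit time as
  the comparable quantity; close sequence pairs therefore carry large
  weights ($1/t$), and the distribution of $r_{ij}$ under neutrality is far
  from the textbook null for independent observations — sequence pairs are
  phylogenetically dependent and a handful of recently diverged pairs can
  dominate every column.
* Because of this, significance is *only* meaningful against an empirical
  null: `buildNull()` simulates neutrally evolving alignments **on the same
  tree** with stationary residue frequencies estimated from the data, scores
  all their column pairs identically, and pools the coefficients
  (default cap $10^5$). The observed $r_{ij}$ is then assigned a one-tailed
  exceedance probability; `alpha = 0.001` is the study-scale default.
* Significance is one-tailed: compensatory covariation predicts high
  positive correlation. Negative correlations are reported but not flagged.

## Divergence-time modes

`divergenceTimes()` supports three estimators:

* `li_ks` — Li-type corrected synonymous substitutions computed from a
  matched in-frame CDS alignment (via `seqinr::kaks`). This is the
  estimator of choice on real data: synonymous divergence is approximately
  neutral and bounded away from zero between distinct organisms. Saturated
  or undefined estimates are replaced by the largest finite entry;
  identical coding sequences get 0 before flooring.
* `patristic` — branch-length sums on a supplied tree; used throughout the
  synthetic test bed, where the tree is known exactly.
* `poisson_protein` — $-\ln(1-p)$ on protein p-distances, a fallback when
  neither CDS nor tree is trusted.

All modes floor off-diagonal entries at `epsilon = 1e-4` (substitutions per
site) before division. The floor only matters for (near-)identical
sequences, which the preprocessing (`deduplicate()`,
`dropWithinSpeciesDuplicates()`) largely removes.

## Numerical choices

* **Mid-p exceedance.** The empirical null is discrete: alignments
  simulated on one tree produce exact ties (duplicated columns give
  $r = 1$ exactly, and low-substitution columns repeat a finite set of
  patterns). Counting whole atoms as exceedances makes the plain add-one
  estimator visibly conservative at `alpha = 0.001`, so p-values use the
  mid-p form $p = (\#\{r_0 > r\} + \#\{r_0 = r\}/2 + 1)/(n+1)$, which is
  calibrated on neutral data (the acceptance suite measures the realised
  false-positive rate) and can never return 0.
* **Threshold convention.** The stored null threshold is the order
  statistic at rank $\lceil (1-\alpha)(n+1) \rceil$ (capped at $n$), the
  value a new draw exceeds with probability $\le \alpha$; decisions are
  made on p-values, the threshold is descriptive.
* **Skip semantics.** Pairs with fewer than 3 jointly unmasked sequence
  pairs, or with a constant vector on the joint mask, are recorded with a
  `skip_reason` (`insufficient_overlap`, `zero_variance`), never silently
  dropped.
* **Tie-breaks.** Modal residues (sector statistics) break frequency ties
  alphabetically; NJ joins are delegated to `ape::nj`, with negative branch
  lengths clamped to 0.

# Phylogenetic pair bootstrap

Each replicate draws `ceiling(fraction * n)` sequences (default
`fraction = 0.8`) **without replacement**, prunes the tree (patristic
distances among retained leaves are preserved exactly), re-derives the null
on the subsample at reduced simulation effort, and re-scores the base pairs
at the same `alpha`. Support is the fraction of replicates in which a pair
is re-detected; retention requires support strictly above 0.70. Design
notes:

* Sampling *with* replacement would create zero-divergence duplicates the
  statistic cannot use, hence without replacement.
* A pair's detection depends only on its own coefficient against the null,
  so per-replicate work is restricted to the base pairs' columns; this is
  exactly equivalent to a full rescan followed by intersection.
* The replicate null is re-derived (rather than reusing the full-data null)
  because subsampled alignments have different size and tie structure; the
  per-replicate effort (`nullSim`, `nullSamples`) trades precision for
  time and is configurable.
* Replicate $r$ uses seed `seed + r` (null: `seed + nReps + r`), so
  replicates are independent and order-insensitive.

# Networks

Retained pairs form an undirected graph (nodes labelled
`protein:site`, support kept as edge metadata, duplicates collapsed, no
self-loops). Centralities are hop-based: integer degree; closeness
$(n_c - 1)/\sum d$ computed within each connected component (0 for
singleton components; the unnormalised reciprocal farness is also
reported, since conventions differ); betweenness as the unnormalised
shortest-path pass-through sum. The acceptance suite checks all three
against exhaustive path enumeration on every connected graph with up to 6
nodes.

# Sector statistics

For a site group $S$, with $f$ the frequency of the modal residue and $q$
its background frequency over the whole alignment,

$$D_i = f\ln\frac{f}{q} + (1-f)\ln\frac{1-f}{1-q}, \qquad
  I_S = D_S - \sum_{i \in S} D_i,$$

where $D_S$ applies the same two-outcome relative entropy to the *joint*
modal pattern: $f_S$ is the fraction of sequences carrying the modal
residue at every site of $S$ simultaneously, and the group background is
$q_S = \prod_{i \in S} q_i$. Interpretive decisions, made where the
textbook formulation of such group entropies is ambiguous:

* $q_S$ as the product of per-site backgrounds is the independence
  expectation of the joint modal pattern, which makes $I_S$ a genuine
  excess-covariation measure (it reduces exactly to $D_i$ and $I_S = 0$
  for singletons — tested exactly).
* Backgrounds are computed from the combined alignment of the clades under
  comparison, putting both groups on one reference.
* Sequences gapped at any site of $S$ are excluded from $f_S$'s
  denominator; $0\ln 0 = 0$ throughout.

The independence test compares
$\Theta = I_{S}(g_1 \cup g_2) - (I_S(g_1) + I_S(g_2))$ with a null of
$\Theta$ over `nRandom` (default 1000) pairs of disjoint random site
sets of the same sizes drawn from the same protein-domain pool; the
z-score against the null mean/sd gives a two-sided normal p-value, and the
groups are called independent when $p \ge 0.05$. GroEL domain ranges in
the conventional E. coli numbering ship as `groELDomains()` but are plain
configuration.

# Structure statistics

Residue proximity uses the minimum Euclidean distance over all
carbon–carbon atom pairs ("proximal carbons"; an alpha-carbon-only mode
exists for sensitivity checks), with 4 Å as the conventional contact
cutoff. Group compactness is the mean pairwise minimum-carbon distance;
its significance is the add-one rank of the observed compactness among
random equal-size residue sets from a stated pool. Secondary-structure
enrichment compares observed helix/strand/coil counts of a site group to
the chain composition with a plain chi-square (no continuity correction);
classes with zero expectation are dropped with the degrees of freedom
reduced, and totals are conserved exactly.

# The synthetic-data module

The generator provides the null engine and the test substrate:

* `simulateTree()`: pure-birth trees rescaled so the mean root-to-tip path
  equals `depth` (substitutions/site).
* `evolveAlignment()`: site-independent continuous-time evolution with
  uniform exchangeability and configurable stationary frequencies (an
  F81-style process — chosen because the null needs covariation-free
  neutrality, not biochemical realism). For a planted pair with coupling
  $\rho$, every substitution event at one site is mirrored at the other
  with probability $\rho$; the mirrored state is *the same state*
  (identity pairing), so $\rho = 1$ yields an exactly duplicated column —
  the strongest covariation signature the statistic can see, and the one
  effect size that is interpretable against the heavily inflated
  phylogenetic null — while $\rho = 0$ is exact neutrality.
* `emitCDS()`: reverse translation with a per-cell probability of a
  non-canonical synonymous codon, giving tunable synonymous divergence for
  the `li_ks` mode without touching the protein sequence.
* `syntheticStructure()`: single-carbon residues; designated groups inside
  a ball of diameter just under `clusterRadius` (default 4 Å), background
  uniform in a cube sized so its mean pairwise distance is the target
  `spread` (default 40 Å, the background regime of a globular chain).

Default profile: 30 taxa, depth 0.3, 200 columns, uniform frequencies —
chosen so mean pairwise divergence lands in the 0.30–0.40 band typical of
deep bacterial protein alignments, the regime in which this class of
detector is considered reliable.

What the generator does **not** emulate: indels (gaps only enter through
real data), across-site rate heterogeneity, amino-acid exchangeability
structure, alignment error, and paralogy. Passing tests therefore
demonstrate internal correctness and calibration under the declared model,
not robustness to those real-data complications.

# Test and acceptance problem sizes

The statistical checks run at deliberately chosen sizes: null calibration
on 20 neutral datasets of 30 sequences x 200 columns with a per-dataset
null of 10 simulated alignments (so null-quantile noise averages out);
power at couplings 0/0.5/1 with 3 planted pairs per coupling in each of 20
datasets at tree depth 0.5; bootstrap support at 100 replicates; the
independence test's type-I error over 200 datasets at `nRandom = 200`.
Unit fixtures are smaller. At small scale (say 12–15 sequences, 60
columns) the null's tie mass near $r = 1$ exceeds `alpha = 0.001`, and
even a perfectly duplicated column pair cannot be significant — that is a
real property of the method at low sample size, and the reason analyses of
this kind are restricted to clades with enough sequences.

# Known limitations

* Power at intermediate coupling is modest: the $1/t$ weighting
  concentrates effective degrees of freedom on recently diverged sequence
  pairs, and only near-perfect covariation stands far out of the
  phylogenetic null. The calibration, not the power, is the guaranteed
  property.
* The null shares the data's tree; misspecified trees shift both, which
  protects calibration but blurs interpretation.
* `li_ks` saturates for deep divergences; saturated estimates are replaced
  by the matrix maximum, compressing the correction at the deep end.
* The independence test's normal approximation is checked empirically at
  the study conditions; strongly skewed null shapes (tiny pools, extreme
  group sizes) may miscalibrate it, and the degenerate-null case errors
  rather than guessing.
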