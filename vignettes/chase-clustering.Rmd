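---
title: "Chase clustering of presence-absence community matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chase clustering of presence-absence community matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasecluster)
```

## The problem

Site-by-species incidence matrices are the common currency of community
biogeography: rows are places (archaeological sites, survey plots,
samples), columns are taxa, and a cell records whether the taxon was
observed there. Two questions recur. Do sites fall into compositional
groups, and do those groups follow geography? Agglomerative methods that
mix geographic distance into the dissimilarity answer the second question
by construction — they cannot reveal groupings that cross geographic
boundaries, such as the compositional convergence that domesticated
livestock impose on distant regions. This package pairs two estimators so
the questions can be separated:

* **chase clustering** — an unconstrained, similarity-only partition
  optimizer that infers the number of clusters from the data, and
* **geography-constrained Ward clustering** — the conventional
  ClustGeo-style baseline, built on a convex mixture of compositional and
  geographic dissimilarities,

together with the comparison apparatus used around them: adjusted-Rand
agreement between partitions, Jaccard turnover between epochs at
radius-aggregated localities, and a planted-partition generator that makes
every stage testable end to end.

## The chase model

Let $S$ be the *chase matrix*: pairwise compositional similarities between
sites (Jaccard by default; Simpson and Ochiai are options). A partition
$P$ of the sites is scored by the penalized coherence objective

$$F(P) \;=\; \sum_{c \in P} \sum_{\{i,j\} \subseteq c} \bigl(S_{ij} +
\gamma\bigr) \;-\; \rho \,\#\{c : |c| = 1\},$$

where the inner sum runs over unordered within-cluster pairs, $\gamma \le
0$ is a regularization added to every pair term, and $\rho > 0$ is a fixed
penalty per single-site cluster. A pair of sites is worth keeping together
exactly when its similarity exceeds $|\gamma|$, so $\gamma$ acts as an
interpretable overlap threshold: at $\gamma = 0$ any positive overlap
favours merging and the optimum collapses to the connected components of
the similarity graph; as $\gamma$ becomes more negative, weakly
overlapping groups split and the optimal number of clusters grows. The
singleton penalty suppresses trivial one-site "clusters", which would
otherwise be free of any negative pair terms.

The published description of this estimator leaves the exact functional
form to supplementary material we do not reproduce; the form above is a
reconstruction chosen because (i) it reproduces the qualitative behaviour
that motivates the method — full merging at $\gamma = 0$, progressive
splitting as $\gamma$ decreases, suppression of singletons — and (ii) the
change in $F$ under a single-site move is local to the two affected
clusters, which makes stochastic search cheap. A per-cluster *mean* form
(mean pair similarity plus $\gamma$) is available behind
`chase_control(pair_form = "mean")` for sensitivity checks; it weakens the
size-dependence of cluster scores but removes the additive decomposition
that makes $\gamma$ a pair-level threshold.

### Search

`chase()` maximizes $F$ by multi-start stochastic search. For each
requested $k$ in `k_min:k_max`:

1. **Seeding.** $k$ seed sites are drawn sequentially with probability
   proportional to species richness (rich assemblages carry the most
   compositional information), rejecting candidates whose similarity to an
   already-chosen seed exceeds `seed_similarity_cap` (default 0.5, relaxed
   in +0.1 steps if nothing qualifies) so seeds are compositionally
   distinct. Every other site is then *chased* into the most similar seed
   cluster.
2. **Shuffling.** `n_shuffles` proposals each move a uniformly random site
   to a uniformly random target among the currently non-empty clusters
   plus at most one dormant cluster. The change $\Delta F$ is computed
   incrementally (exactly; this is tested against full recomputation).
   Improvements are always accepted; deteriorations are accepted with
   Metropolis probability $e^{\Delta F / T}$ under a geometrically cooled
   temperature $T$. Clusters may empty and die, so the effective $k$ is
   data-driven. The best labelling ever visited is returned.
3. **Selection.** The best partition across all starts and all requested
   $k$ wins; ties break toward fewer effective clusters, then smaller
   requested $k$ (parsimony). Labels are canonicalized (decreasing size,
   then smallest member site id) so runs are comparable.

**Why the temperature matters.** The deepest barrier on the path between
two partitions is a transient singleton: absorbing a doomed cluster's last
member first *creates* a one-site cluster, costing the singleton penalty
minus whatever pair terms the lone site already shares with its
destination. Pure greedy acceptance can never cross this barrier, so it
systematically stalls at partitions that are too fine — on small random
instances it reaches the enumerated global optimum only about half the
time. With a starting temperature on the scale of the net barrier
(`anneal_t0 = 3` against the default penalty of 5) the same search budget
attains the exhaustive optimum essentially always, which is why annealed
acceptance is the default and greedy (`anneal_t0 = 0`) is the opt-in.

### Reproducibility

One integer seed drives everything. It expands into an independent
substream per (gamma, k, start), so results are bit-identical across runs
and invariant to the order in which starts are executed. The shuffle loop
is compiled code but draws from R's own RNG, so `set.seed()` semantics
apply throughout.

### Stability

Because the search is stochastic, `chase()` also reports how consistently
sites land in the same cluster across the random starts at the winning
$k$: each run's clusters are matched one-to-one to the best partition by
maximum overlap (an exact assignment solved by dynamic programming over
cluster subsets, feasible because $k \le 15$), and a site's stability is
the fraction of runs in which it lands in its matched cluster.
`consistent_fraction` is the share of sites with stability $\ge 0.9$ — a
deliberately strict cutoff: a site must co-travel in at least 90% of
starts to count as consistent.

## The constrained Ward baseline

`ward_geo()` mixes a compositional dissimilarity $D_0$ (Euclidean distance
between binary rows, i.e. the square root of the assemblage symmetric
difference) and a geographic one $D_1$ (great-circle kilometres, haversine
on a sphere of radius 6371.0088 km) as $(1-\alpha) D_0^* + \alpha D_1^*$.
Kilometres and occupancy units are not commensurable, so both matrices are
first normalized by their maximum off-diagonal entry — this makes $\alpha$
directly interpretable on $[0,1]$ (raw mixing is available via
`normalize = FALSE`). Ward agglomeration uses the Lance–Williams recursion
on squared dissimilarities (the `ward.D2` convention; merge heights are
verified against `stats::hclust` to $10^{-9}$), with ties broken toward
the lowest leaf indices so trees are deterministic.

$k$ is not inferred: it is fixed, conventionally to the chase result, so
the two methods are compared like for like. With `alpha = "auto"` the mixing
weight is scanned on a grid (step 0.01, 101 values); each candidate tree
is cut at $k$ and scored by the explained pseudo-inertia
$Q = 1 - \sum_c I(c) / I(\text{all})$ with
$I(A) = \tfrac{1}{|A|}\sum_{i<j \in A} D_{ij}^2$, evaluated separately on
the normalized compositional matrix ($Q_0$) and the geographic one
($Q_1$). The selected $\alpha$ maximizes $Q_0 + Q_1$ (ties to the smallest
$\alpha$, favouring composition). Whether "variance explained" should be
assessed on one matrix or both is genuinely open; maximizing the sum
treats both sources symmetrically, and the max–min alternative is a
one-flag switch (`criterion = "min"`).

## Turnover at localities

`turnover()` aggregates the sites of two epochs jointly into localities:
two sites share a locality iff they are connected by a chain of
great-circle steps each within `radius_km` (default 50 km). "Within a
radius" does not by itself fix a grouping rule; single linkage is used
because it is deterministic and order-free, at the cost of chaining —
three sites strung 30 km apart form one locality even though the end
points are 60 km apart. Complete linkage (every pair within the radius) is
the documented alternative. Localities with records in both epochs get the
Jaccard turnover of their pooled assemblages,
$d_J = (\text{gained} + \text{lost}) / |\text{union}|$, with the count
identities (`shared + gained = n_holocene`, etc.) tested on random sets.
By convention domesticates stay in the later epoch's assemblage; pass a
wild-only matrix to measure wild turnover.

## What the synthetic worlds emulate — and what they do not

`simulate_sites()` plants $G$ disjoint regional species pools (default 5
regions × 40 species) plus 10 cosmopolitans. A site detects each species
of its own region with $p_{det} = 0.6$, each cosmopolitan with $p_{cos} =
0.3$, and each foreign species with a leakage $p_{leak} = 0.02$;
coordinates scatter isotropically (sd 1.5°) around region centres at least
$10\times$ that apart. These defaults give within-region Jaccard
similarity near 0.4 and between-region similarity near 0.02 — a clearly
planted but noisy partition whose expected values are analytically
tractable because the pools are disjoint by construction.
`overlay_domesticates()` adds 6 taxa that every site acquires with
probability 0.5 *regardless of region* — the homogenizing signal.
`simulate_epoch_pair()` replaces a `tau_loss` fraction of each regional
pool and adds `tau_gain` novel species, for a pool-level Jaccard turnover
of $(\tau_l + \tau_g)/(1 + \tau_g)$ in closed form. Both epochs reuse the
same per-site coordinates, and the epoch-pair coordinate noise defaults to
0.1° (~11 km) so each region aggregates into one multi-site locality: the
union of 12 sites at $p_{det} = 0.6$ recovers essentially the whole pool
(coverage $1 - 0.4^{12}$), which is what makes locality-level turnover
comparable to the pool closed form. The turnover calibration switches
leakage off, because foreign-pool detections are redrawn independently in
each epoch and would register as spurious gains and losses that the closed
form does not describe.

`simulate_nested()` adds a second structural scale — super-regions whose
subregions share part of their pool (within-subregion similarity ≈ 0.5,
cross-subregion within a super-region ≈ 0.12, cross-super-region ≈ 0.01)
— so that the number of clusters selected by `chase()` steps upward as
$\gamma$ moves through those thresholds. This is the fixture for the
gamma-monotonicity checks.

What these worlds deliberately lack: spatial autocorrelation within
regions, uneven sampling effort, taxonomic error, abundance structure, and
gradual (non-block) compositional gradients. Passing recovery tests on
them shows the estimators work when their assumptions hold; it does not
show robustness to the messiness of real zooarchaeological data, where
detection is confounded with taphonomy and sampling intensity.

## Numerical choices and degenerate inputs

* All row/column orderings are lexicographic in the C locale (radix
  sort), so nothing depends on input order or platform collation.
* Similarity matrices are symmetrized exactly and carry a unit diagonal;
  empty assemblages are rejected (the richness filter runs first).
* The adjusted Rand denominator vanishes when both partitions are
  trivial; the convention is 1 when they are identical, 0 otherwise.
* `mixed_dissimilarity()` refuses all-constant matrices (normalization
  undefined).
* Ward ties break toward the lowest leaf pair; chase chase-in ties toward
  the lowest cluster index; global-best ties toward fewer clusters.
* Richness filtering is idempotent, and is re-applied after domesticate
  removal (a site whose assemblage was mostly livestock can fall below
  the minimum once they are removed; whether to re-filter is a genuine
  pipeline ambiguity and the re-applied choice is documented here).
* A generated site falling below the richness minimum is redrawn at most
  100 times, then the generator errors rather than silently biasing
  detection upward.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
full battery completes in minutes on one core: the planted world at its
default 60 sites (40 starts × 3 000 shuffles per requested $k$), the
nested fixture at 48 sites, exhaustive-optimum comparisons on 8-site
instances against enumeration of all ≤3-block partitions, and the turnover
calibration at 200-species pools. The method's conventional operating
point for real data (250 starts × 10 000 shuffles, $k$ searched 2–15)
remains the package default.

## Known limitations

* The objective is a reconstruction; analyses that depend on its exact
  supplementary definition may differ quantitatively (cluster counts
  along a $\gamma$ sweep are the most sensitive output).
* Stochastic search carries no optimality certificate beyond the
  small-instance enumeration checks; report `consistent_fraction` and, for
  publication-grade runs, increase `n_starts`.
* Single-linkage locality aggregation chains; with dense site networks,
  localities can grow beyond the nominal radius.
* The dynamic-programming cluster matching is exact but exponential in
  the smaller cluster count; it is capped at the package's $k \le 15$.
* Great-circle distances use a spherical Earth (IUGG mean radius);
  ellipsoidal corrections (~0.3%) are ignored.
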