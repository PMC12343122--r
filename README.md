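# chasecluster

Compositional clustering of presence–absence community matrices, for
biogeographers and community ecologists who want to know whether their
sites group by *what lives there* rather than by *where they are*.

The motivating use case is zooarchaeological: site-by-mammal incidence
matrices spanning the Late Pleistocene–Holocene transition, where
cross-regional livestock can make geographically distant assemblages
compositionally similar — a signal that geography-constrained clustering
is structurally unable to see. The methods are general: any binary
site × taxon matrix with site coordinates works (survey plots, microbiome
samples with spatial metadata, etc.).

## What is in the box

**Chase clustering** (`chase()`) — an unconstrained partition optimizer on
the pairwise site-similarity ("chase") matrix *S*. A partition *P* is
scored by

    F(P) = sum over clusters c of sum over pairs {i,j} in c of (S_ij + gamma)
           - rho * (number of one-site clusters)

with gamma ≤ 0 a pair-level regularization and rho a singleton penalty.
Clusters are seeded from richness-weighted, compositionally distinct
sites, remaining sites are "chased" into their most similar cluster, and
assignments are then shuffled stochastically (simulated-annealing-style
acceptance, best-visited retention) over a range of requested *k*.
Clusters can empty and die, so the effective number of clusters is
inferred from the data; more negative gamma yields more clusters. Results
are bit-reproducible from one integer seed.

**Constrained Ward baseline** (`ward_geo()`) — Ward agglomeration
(Lance–Williams, `ward.D2` convention) on the convex mixture
`(1 - alpha) * D0* + alpha * D1*` of max-normalized compositional
(Euclidean occupancy) and geographic (great-circle km) dissimilarities,
with `alpha` selected on a 0.01 grid by explained pseudo-inertia.

**Comparison & turnover** — adjusted Rand index and contingency reports
(`adjusted_rand_index()`, `compare_partitions()`), and Jaccard faunal
turnover between epochs at 50 km radius-aggregated localities
(`turnover()`, GeoJSON export included).

**Data handling** — long-form occurrence and site tables in/out, the
minimum-unique-identification rule (drop a genus record where a congeneric
species record exists at the same site), presence–absence reduction,
richness filtering (default: drop sites with fewer than 5 species), and
domesticate/wild matrix splitting.

**Synthetic worlds** (`simulate_sites()`, `overlay_domesticates()`,
`simulate_epoch_pair()`, `simulate_nested()`) — planted-partition
generators with regional pools, cosmopolitans, a cross-regional
domesticate overlay, and epoch pairs with closed-form expected turnover,
so the whole pipeline is testable without any external data.

A command-line front end covering the pipeline
(`simulate` / `chase` / `sweep-gamma` / `ward` / `turnover` / `compare`)
is installed at `inst/cli/chasecluster.R`:

    Rscript "$(Rscript -e 'cat(system.file("cli","chasecluster.R",package="chasecluster"))')" \
        chase --occurrences occ.csv --sites sites.csv --epoch holocene \
        --gamma -0.1 --seed 1 --out results/

## Worked example

```r
library(chasecluster)

cfg <- synth_config()                       # 5 regions x 12 sites
syn <- simulate_sites(cfg, seed = 42)
syn$matrix
#> site_matrix: 60 sites x 210 taxa
#>   richness: min 23, median 31, max 40
#>   fill: 14.6%

fit <- chase(syn$matrix, gamma = -0.1, k_min = 2, k_max = 10, seed = 1,
             control = chase_control(n_starts = 40, n_shuffles = 3000))
fit
#> Chase clustering
#>   60 sites, metric jaccard, gamma = -0.1
#>   selected k = 5 (requested 5), objective = 79.0603
#>   cluster sizes: 12, 12, 12, 12, 12
#>   stability: 68.3% of sites consistent (>= 0.9) across 40 starts

adjusted_rand_index(fit$best$labels, syn$true_labels)
#> [1] 1
```

The optimizer was asked for anything between 2 and 10 clusters and
settled on 5 — the planted regional structure — with perfect agreement
(ARI = 1) against the generator's true labels. The objective is the
penalized within-cluster coherence; the stability line says 68% of sites
landed in the same (matched) cluster in at least 90% of the 40 random
starts.

The constrained baseline, cut at the chase *k*:

```r
ward_geo(syn$matrix, k = fit$best$k_effective)
#> Geography-constrained Ward clustering
#>   k = 5, alpha = 0.00 (Q0 = 0.460 composition, Q1 = 0.988 geography)
#>   cluster sizes: 12, 12, 12, 12, 12
```

Here geography and composition agree (the generator plants them
concordantly), so composition alone (`alpha = 0`) already explains the
geographic structure: the same five regions, 99% of geographic inertia.

Turnover between a simulated epoch pair (pool replacement
`tau_loss = tau_gain = 0.2`, expected pool turnover 0.4/1.2 = 0.333):

```r
ep <- simulate_epoch_pair(synth_config(species_per_region = 200, p_leak = 0),
                          seed = 42)
turnover(ep$pleistocene, ep$holocene)
#> Faunal turnover at 5 paired localities
#>   Jaccard distance: min 0.320, mean 0.322, max 0.324
```

Each region's 12 sites aggregate into one 50 km locality per epoch; the
pooled assemblages show the designed one-third species replacement (the
small deficit below 1/3 is the persistent cosmopolitan pool).

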