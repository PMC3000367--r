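# canet — cross-species discovery of conserved active subnetworks

`canet` finds **conserved active subnetworks**: sets of ortholog clusters
that are densely interconnected in the weighted functional linkage networks
of *two* species and coherently differentially expressed in *both*. It is
aimed at comparative systems biology — e.g. matching a mouse and a human
differential-expression compendium profiled under analogous conditions — where
single-species module searches drown in the small-world connectivity of
dense interaction networks. Requiring the same module, with the same
direction of regulation, in two networks linked by orthology acts as a
strong noise filter.

## The method

Inputs per species are a weighted functional linkage network (edge weights =
confidence in `(0, 1]`) and a normalized activity profile in `[-1, +1]`
(signed fold changes, non-significant genes at 0, directional extremes at
±1), joined by an InParanoid-style ortholog-cluster map. Everything is mapped
into cluster space: paralog edges are averaged (a missing edge counts as 0)
and a cluster takes its strongest member activity.

Each cluster gets an activity score from the two species' activities *m*, *h*:

* **conserved**: `sign(m·h) · √|m·h|` — geometric mean of the magnitudes,
  signed by directional agreement;
* **species-specific**: `|m − h|`;
* **single-species**: `m`.

Subnetworks are grown greedily from every differentially active seed. The
candidate pool is the seed's *functional neighbourhood*: all clusters whose
best path from the seed has confidence (product of edge weights) above a
per-species threshold (defaults 0.3 / 0.8), pooled over both networks. Each
step adds the candidate — together with the clusters on its stored best
path, which lets inactive bridging genes in — that maximizes the mean member
score, provided the mean stays above a cutoff (default 0.15) and the induced
subgraphs keep a minimum average **weighted clustering coefficient** in both
species (sum of neighbour-pair edge weights over neighbour pairs; defaults
0.1 / 0.2). Mostly-overlapping results (>60% shared members) are
deduplicated, and each subnetwork is coloured green / red / yellow by a 2×
majority of its members' shared regulation direction.

Significance is empirical: activities are shuffled among network genes
(independently per species), discovery is re-run 5 times, and the real count
is compared with the random mean (signal-to-noise). Hypergeometric
enrichment with Bonferroni correction annotates member sets.

A synthetic two-species benchmark generator (`generate_benchmark()`) plants
conserved and species-specific modules with known ground truth — including
paralogs and a gene-space/cluster-space round trip — so the whole method is
testable without any external download.

## Worked example

```r
library(canet)

bm <- generate_benchmark(benchmark_spec(rng_seed = 1))  # 300 clusters, 3 + 2 planted modules
cs <- benchmark_cluster_space(bm)                       # map gene space -> ortholog clusters

found <- discover_subnetworks(cs$net_a, cs$activity_a,
                              cs$net_b, cs$activity_b, search_config())
print(found)
```

```
subnetwork_set: 3 subnetwork(s) [conserved mode, score cutoff 0.15]
   seed size     score      cc_a      cc_b color
1 C0020    8 0.7872744 0.5383441 0.6299909 green
2 C0037    8 0.7863828 0.7705634 0.6822441   red
3 C0079    8 0.7727027 0.6241241 0.4955188   red
```

Each row is one subnetwork: its seed cluster, size, mean conserved activity
score (here ≈0.78 — the planted modules carry strong, sign-consistent
activity in both species), the average weighted clustering coefficients of
its induced subgraphs in species A and B (all far above the 0.1/0.2
thresholds), and its colour (`green` = up-regulated in both species, `red` =
down-regulated). The three subnetworks are exactly the three planted
conserved modules; the two planted species-specific modules are correctly
*not* reported in conserved mode (their species-B activity is zero, so their
conserved scores vanish).

```r
rs <- randomization_experiment(cs$net_a, cs$activity_a,
                               cs$net_b, cs$activity_b,
                               search_config(), R = 5, base_seed = 1007)
print(rs)
```

```
randomization: 3 real subnetwork(s) vs 0.20 +/- 0.45 random (R = 5)
  signal-to-noise 15; mean size real 8.00, random 4.00
```

Shuffling the activity labels destroys the planted signal: the 5 random runs
average 0.2 subnetworks against 3 real ones (signal-to-noise 15), the
real-versus-random contrast that certifies the discoveries are not a
connectivity artifact.

```r
recovery_metrics(found, bm$truth, type = "conserved")$recall
#> [1] 1
```

A command-line wrapper covering `simulate`, `discover`, `randomize`,
`enrich` and `recover` lives at `inst/cli/canet.R`:

```sh
Rscript inst/cli/canet.R simulate --out bench --seed 1
Rscript inst/cli/canet.R discover --net-a bench/net_a.tsv --net-b bench/net_b.tsv \
    --activity-a bench/activity_a.tsv --activity-b bench/activity_b.tsv \
    --orthology bench/orthology.tsv --out run
Rscript inst/cli/canet.R recover --subnetworks run/subnetworks.tsv --truth bench/truth.json
```

Every run writes a `manifest.json` (options, input digests, seeds, versions,
wall time) for reproducibility.

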