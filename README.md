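# DrugNetEvo

Complex-network analysis of how drug interaction knowledge evolves across
versioned drug-database releases, and of how fragile that analysis is to
the interactions we have not discovered yet.

## The problem

Drug databases record only *positive* knowledge: the drug–drug
interactions (DDI) and drug–target interactions (DTI) that experiments
have confirmed so far. A missing edge is not evidence of absence — it may
simply be an interaction nobody has tested. Network-based methods for drug
repositioning and interaction prediction rank drugs by centrality on these
networks, so two questions matter:

1. **Evolution.** As releases accumulate knowledge, do the DDI and DTI
   networks keep the topology (sparse, power-law degrees, short paths)
   that complex-network methods assume? DDI networks, in particular,
   densify dramatically across releases (density *r* growing from ~0.019
   to ~0.128), while bipartite DTI networks stay sparse
   (*r* ~ 7×10⁻⁴).
2. **Robustness.** If a fraction *q* of the currently unknown pairs turned
   out to be real interactions, how much would centrality-based drug
   rankings move?

`DrugNetEvo` implements the full pipeline:

* **ingest** — streaming parser for DrugBank-dialect XML releases and the
  approved-human-drug filter (keep `approved`, drop `withdrawn` /
  `vet_approved`; strict mode also drops `investigational` /
  `experimental`).
* **build** — monopartite undirected DDI and bipartite directed DTI
  networks (`igraph`-backed S4 class `InteractionNetwork`), plus an
  implicit, exactly-counted non-edge universe with uniform sampling.
* **stats** — summary metrics: average degree ⟨d⟩ = 2|E|/|V|, local
  clustering ⟨c⟩, density r = 2|E|/(|V|(|V|−1)), average path length ⟨s⟩
  and diameter φ on the largest component; centralities: degree,
  betweenness (Brandes and a literal pair-indicator variant), closeness
  (component-scaled), eccentricity, eigenvector (Wη = λη by shifted power
  iteration), PageRank.
* **powerlaw** — discrete/continuous maximum-likelihood fits of
  P(x) ∝ x^(−α) with Kolmogorov–Smirnov selection of the lower cutoff
  (Clauset–Shalizi–Newman), plus a binned log–log slope.
* **benford** — first-significant-digit tests against Benford's law
  P(f) = log₁₀(1 + 1/f), with χ², Wasserstein and sum-of-squared-deviation
  distances, as a data-quality signal on centrality distributions.
* **robustness** — the edge-injection simulation: add
  m = round(q·|Ē|) edges drawn uniformly from the non-edge universe Ē,
  recompute a centrality, and track the Kendall τ between node rankings
  and the change in the fitted exponent α over R replicates per rate q.
* **synthetic** — a seeded generator of versioned DDI series (power-law
  seed degrees, preferential densification to a density schedule) and
  bipartite DTI networks (preferential-attachment growth), serialized as
  DrugBank-dialect XML so everything above is testable with no downloads.

Real releases are optional input: anything in the supported XML dialect
parses, and real DrugBank files are a superset of the dialect.

## Worked example

```r
library(DrugNetEvo)

cfg <- syntheticConfig(nDrugs = 100, nTargets = 80, nVersions = 2,
                       ddiDensitySchedule = c(0.02, 0.128),
                       dtiMeanDegree = 3.6, seed = 1)
nets <- generateDdiSeries(cfg)          # two DDI versions
dti  <- generateDti(cfg)                # one DTI layer
dir  <- tempfile()
paths <- writeFixtureXML(list(list(nets[[1]], dti),
                              list(nets[[2]], dti)), dir,
                         fileNames = c("v1.xml", "v2.xml"))

reports <- runPipeline(setNames(paths, c("v1", "v2")))
evolutionTable(reports)[, c("version", "network", "n_nodes", "n_edges",
                            "density", "avg_degree", "avg_path_length")]
```

```
  version network n_nodes n_edges    density avg_degree avg_path_length
1      v1     ddi     100      99 0.02000000       1.98        3.928421
2      v1     dti     180     324 0.02011173       3.60        3.879231
3      v2     ddi     100     634 0.12808081      12.68        1.978182
4      v2     dti     180     324 0.02011173       3.60        3.879231
```

Reading the table: the DDI layer densifies from its scheduled density 0.02
to 0.128 (average degree 1.98 → 12.68) and its average shortest path
collapses from 3.93 to 1.98 — the network is becoming too dense for
community- or ranking-based analysis — while the DTI layer is unchanged
across the versions. The same trend, at release scale, is what motivates
treating dense DDI networks with caution.

How stable is a degree ranking under unknown interactions?

```r
rc <- runRobustness(dti, centrality = "degree",
                    qGrid = seq(0.01, 0.1, by = 0.01), R = 100, seed = 1)
head(curveTable(rc)[, c("q", "tau_mean", "tau_var", "n_injected_edges")], 3)
```

```
     q  tau_mean      tau_var n_injected_edges
1 0.01 0.8050695 0.0002278773               77
2 0.02 0.7074940 0.0004423368              154
3 0.03 0.6583312 0.0007631166              230
```

τ decays steadily as the assumed unknown-interaction rate grows: even a 1%
injection moves the ranking measurably (τ ≈ 0.81 on this 180-node
fixture), and the decay with q is monotone — exactly the fragility the
simulation is designed to expose.

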