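---
title: "Evolution and robustness of drug interaction networks"
author: "DrugNetEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution and robustness of drug interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DrugNetEvo)
```

## Scope and model

`DrugNetEvo` analyses two network views of a versioned drug database:

* the **DDI network** — monopartite, undirected, unweighted; nodes are
  drugs, an edge means a reported drug–drug interaction;
* the **DTI network** — bipartite, directed drug → target, unweighted;
  one partition holds drugs, the other biological targets
  (proteins/enzymes).

Both are *positive-knowledge* graphs. The complement of the edge set on
the current node set — all unordered drug pairs without a reported
interaction (DDI), all drug × target pairs without an annotation (DTI) —
is the **non-edge universe**: the space in which future discoveries live.
Every quantity the package computes is a function of one release
snapshot; evolution enters by comparing snapshots across versions.

Interaction type, strength and severity are deliberately out of scope:
edges are binary, and the only per-drug metadata consumed are the group
labels (regulatory status) and target organism needed for filtering.

## Ingestion and the approved-drug filter

Releases are read from a DrugBank-dialect XML (root `drugbank`, repeated
`drug` elements with `drugbank-id`, `name`, `groups/group`,
`drug-interactions/drug-interaction/drugbank-id`, and
`targets/target/{id, organism, known-action}`). Only these paths are
read, so real releases — a superset of the dialect — parse unchanged. The
reader streams the file one `<drug>` element at a time, keeping memory
bounded by the largest single record rather than the multi-gigabyte file.

The analysis population is *approved human drugs*. Two policies are
implemented because drugs frequently carry several labels at once:

* **permissive** (default): keep a drug labelled `approved` unless it is
  also `withdrawn` or `vet_approved`. A drug that is approved *and*
  investigational stays — the extra label records an ongoing trial for a
  new indication, not a lack of approval.
* **strict**: additionally drop anything labelled `investigational` or
  `experimental`.

The permissive reading matches the magnitude of the published per-release
network sizes; the strict one is available as a switch. Target
annotations are restricted to `organism == "Humans"` (case-insensitive,
trimmed). Whether the pharmacologic-action ("known-action") flag should
further restrict targets is left as an option and off by default: the
flag is retained on every record, and nothing in the filtering depends
on it.

Network construction applies **symmetric closure** to DDI listings: an
interaction listed by either partner creates the undirected edge.
Listings are mirrored in principle but not always in practice, and an
undirected network cannot represent a one-sided listing any other way
without silently discarding data. Drugs and targets with no surviving
interaction are omitted from the networks (they would otherwise be
zero-degree nodes carrying no analysable signal), and nodes are ordered
lexicographically so builds are reproducible and diffable.

## Metrics and centralities

The summary statistics are the standard set: average degree
$\langle d\rangle = \frac{1}{|V|}\sum_i d(v_i) = 2|E|/|V|$ (with in-/out-
and per-partition variants for the DTI), average local clustering
$\langle c\rangle$ (zero by construction on bipartite graphs), density
$r = 2|E|/(|V|(|V|-1))$ computed with the total node count for both
network kinds, and average shortest-path length $\langle s\rangle$ and
diameter $\phi$ by BFS. Path statistics are computed on the **largest
connected component of the undirected view**: averaging over disconnected
pairs is undefined, and the published bipartite path lengths are only
reproducible when the directed DTI is traversed as undirected. Nodes of
degree < 2 contribute 0 to $\langle c\rangle$ (their clustering is
otherwise 0/0).

Centralities:

* **degree** (plus in-/out-degree for the DTI);
* **betweenness**, default Brandes (fractional shortest-path counts
  $\sigma_{jk}(v)/\sigma_{jk}$, normalised by $2/(|V|(|V|-1))$). A
  literal **pair-indicator** variant — a pair contributes 1 if *any*
  shortest path between it crosses the node — is kept behind
  `variant = "pair_indicator"`. The two definitions coexist in the
  field's formulations; they agree whenever shortest paths are unique,
  and Brandes is the default because it is the algorithm any
  complexity-conscious analysis actually runs.
* **closeness** $\gamma(v) = (\sum_{u \in C\setminus\{v\}} s(v,u))^{-1}$,
  scaled by $(|C|-1)/(|V|-1)$ so values from different components are
  comparable; singleton components get 0.
* **eccentricity** — the max BFS distance within a node's component.
* **eigenvector** — the principal solution of $W\eta = \lambda\eta$,
  computed per component by power iteration and reported on the largest
  component (0 elsewhere). Bipartite adjacency spectra are symmetric
  ($\pm\lambda$), where plain power iteration oscillates; iterating
  $(W + I)x$ keeps the eigenvectors and guarantees convergence. Defaults:
  tolerance $10^{-10}$ on the sup-norm of successive iterates, 1000
  iterations, error (with the iteration count) on non-convergence.
* **PageRank** on the undirected view, damping 0.85, values summing to 1.

## Power-law fitting

Degree and centrality distributions are fitted with the
Clauset–Shalizi–Newman procedure: maximum likelihood for the exponent
$\alpha$ above a cutoff $x_{min}$, with $x_{min}$ chosen to minimise the
Kolmogorov–Smirnov distance between the tail and the fitted law, ties
broken toward the smaller cutoff. Degrees use the discrete likelihood
(Hurwitz-zeta normaliser, evaluated by direct summation with an
Euler–Maclaurin tail); real-valued centralities use the continuous closed
form $\hat\alpha = 1 + n/\sum\ln(x_i/x_{min})$. Cutoff candidates whose
tail would hold fewer than 10 points are not scanned — tiny tails achieve
small KS distances trivially — but an explicitly requested small-tail
cutoff is honoured and flagged.

Two numerical notes. First, the popular closed-form *approximation* to
the discrete MLE, $\hat\alpha \approx 1 + n[\sum\ln(x_i/(x_{min}-\tfrac12))]^{-1}$,
is accurate only for $x_{min}$ of roughly 6 and above; at $x_{min} = 1$
it is biased by several tenths, so the package always maximises the exact
zeta likelihood (the tests cross-check against `igraph`'s plfit
implementation, which agrees to ~10⁻⁴). Second, the binned log–log
histogram slope (`loglogSlope()`) is provided for the strictly graphical
reading of an exponent; the robustness simulation uses the MLE by
default (`alphaMode = "loglog"` switches).

## Benford first-digit testing

As a data-quality signal, first significant digits of a centrality
distribution are compared against Benford's law
$P(f) = \log_{10}(1 + 1/f)$. Digits are extracted by arithmetic scaling
(locale-independent), and zero or non-finite values are excluded *and
counted*: Benford's law is defined on positive significands, and zero
centralities (e.g. the betweenness of every leaf) would otherwise be
forced into an arbitrary digit. Three distances are reported — Pearson's
$\chi^2$ as a raw statistic (deliberately without a p-value, since the
digit counts of network centralities are not independent draws), the 1-D
Wasserstein distance on the ordered digit support with unit ground
distance, and the sum of squared deviations. All three are zero exactly
when the observed digit proportions equal the Benford proportions, and
the report is invariant under scaling the input by powers of ten.

## The edge-injection robustness simulation

To quantify how fragile a centrality ranking is to undiscovered
interactions, the simulation draws $m = \mathrm{round}(q\,|E_t\setminus E|)$
pairs uniformly *without replacement* from the non-edge universe
($E_t$ = all structurally possible pairs), adds them, recomputes the
centrality, and records (i) the Kendall $\tau$ between the node rankings
before and after, and (ii) the fitted exponent $\alpha$ of the perturbed
distribution. This repeats $R$ times per rate (default $R = 100$) on
seeded substreams, for a grid of rates reaching up to $q = 0.1$.

Design choices that were genuinely open:

* **What q scales.** Reading the rate against the quadratic non-edge
  universe is the interpretation consistent with the injected-edge count
  growing like $n^2$; a mode scaling against the existing edge count
  (`injectionMode = "edges"`) is provided for the alternative reading.
  Neither is asserted as canonical.
* **Tie handling.** $\tau_b$ (tie-corrected) is the default because
  centrality ties — degree ties above all — are pervasive. When a
  reference vector is entirely tied (every node the same degree, as on a
  cycle), $\tau_b$ is undefined; such replicates are reported absent and
  counted, never coerced to 0. The un-corrected $\tau_a$ is available and
  is exactly 0 in that situation (no concordant or discordant pairs
  exist).
* **Exponent per replicate.** $\alpha$ is re-estimated (including its
  cutoff) on each perturbed network by default; a fixed-cutoff option
  exists for strict comparability across replicates.
* **Cost gating.** Degree-based replicates are $O(n^2)$; betweenness
  replicates repeat an all-pairs shortest-path computation and are
  refused above a configurable bound (default 2000 nodes) rather than
  silently consuming hours.

Uniform sampling from the universe never materialises it: ranks among the
non-edges are drawn and decoded against the sorted existing-edge indices
by a monotone fixed-point search, which is exact for sparse and
near-complete networks alike (the tests draw an entire complement and
compare it against brute-force enumeration).

## The synthetic generator

The generator produces the study conditions the analysis assumes, so that
every stage is exercised without an account-gated download:

* **DDI series.** Version 1 draws degrees from a discrete power law
  (default exponent 2.5, truncated at $n-1$), realises them by stub
  matching with self-loop/multi-edge rejection, and is completed to its
  scheduled density by degree-proportional edge addition. Subsequent
  versions grow the same edge set to the next scheduled density —
  accretion as an edge superset — after an optional `removalFraction`
  emulating curation (default 0; the real version history both adds and
  filters, and the removal model is a stand-in, not a claim about how
  curation works). The default density schedule interpolates 0.019 →
  0.128, the span observed between the first and latest releases being
  emulated; each realised density matches its schedule entry to within
  half an edge.
* **DTI layer.** A bipartite preferential-attachment growth process:
  edges arrive one at a time; scheduled arrival steps introduce new
  drugs/targets (so every node enters with at least one edge), otherwise
  endpoints are sampled proportional to degree plus an additive offset
  of 3. The offset tempers rich-get-richer growth; by the Price-model
  heuristic (exponent $\approx 2 + a/c$ with $c \approx 3$ preferential
  edges per node at the default mean degree 3.6) it puts the emergent
  degree exponent near 3, the regime typical of sparse bipartite
  drug–target networks. The realised mean degree $2|E|/|V|$ matches the
  configured value up to edge-count rounding.
* **Serialization.** Networks are written as DrugBank-dialect XML (a DDI
  and DTI layer of the same version can share a file), with each DDI edge
  listed under its lexicographically smaller endpoint — deliberately
  one-sided, so the parser's symmetric closure is exercised on every
  round trip. Output is byte-deterministic given the configuration, and
  `parse → filter → build` reproduces the generated node and edge sets
  exactly. Decoy records (e.g. an experimental-only drug) can be appended
  to test the filter.

One root seed drives everything through fixed-offset substreams
(DDI 11, DTI 22, group labels 33), so partial runs are reproducible and
the group labels of a given drug agree between the DDI and DTI
generators.

**What the generator does not emulate.** Real releases change their node
populations (drugs enter and leave), carry textual interaction
descriptions and severity, have organism diversity, correlated
drug/target memberships, and curation dynamics far richer than uniform
removal. Passing tests on these fixtures therefore demonstrates that the
*machinery* — parsing, construction, statistics, fitting, simulation — is
correct under the assumed statistical regime; it does not validate
scientific claims about any real database, which require the real
releases as optional input.

## Problem sizes and numerical choices

The test-suite fixtures use 30–500 drugs and up to two synthetic
versions; the oracle sweep checks all path metrics, Brandes betweenness
and the eigenvector against brute-force enumeration and dense
eigendecomposition on 200 seeded graphs of at most 12 nodes; power-law
recovery uses 50,000 seeded draws; the robustness acceptance run is a
30-node DTI at $R = 100$ over ten rates. These sizes were chosen so the
full suite completes in about a minute while every statistical check
retains enough power to fail loudly when a formula drifts.

Other numerical details: the Hurwitz zeta is summed to 1000 terms with an
Euler–Maclaurin tail (error ~10⁻¹⁰ in the ranges used); first-digit
extraction guards against floating dust around powers of ten; Kendall
$\tau_b$ delegates to `stats::cor`, with an $O(n^2)$ pair-count oracle in
the tests; JSON/CSV outputs are written with six significant digits.

## Known limitations

* Betweenness on dense, large networks is intentionally gated, not
  approximated; no sampled betweenness is provided.
* The power-law module does not test the power-law *hypothesis* (no
  likelihood-ratio comparison against lognormal/exponential, no
  bootstrap p-value); it estimates parameters.
* Multi-gigabyte real releases parse in bounded memory but not in
  parallel; parsing is single-pass per file with a session-level cache
  keyed by file digest.
* The Benford module implements first-digit analysis only (no
  second-digit or two-digit variants).
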