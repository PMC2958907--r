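---
title: "From a curated pathway map to network motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a curated pathway map to network motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmotif)
```

## The problem

Curated signaling-pathway maps — such as dendritic-cell pattern-recognition
receptor networks drawn in CellDesigner and stored as SBML — encode typed
*process descriptions*: species (proteins, receptors, RNAs, complexes, small
molecules) joined by typed reactions (state transitions, heterodimer
associations, dissociations, transcriptional activations, transports,
inhibitions, translations) with catalytic or inhibitory modifier arcs. Two
questions naturally follow such a curation effort. First, bookkeeping: what
exactly is in the map (species per class, reactions per kind, literature
coverage)? Second, structure: once the map is flattened to a directed graph,
which small regulatory circuits — network motifs — occur more often than
degree-matched chance would predict?

`pathmotif` implements that full path: a tolerant CellDesigner-SBML reader
and canonical writer, a census matching the numbers curation papers print, a
projection of the typed hypergraph-like process description onto a simple
directed graph, exact enumeration of connected subgraphs of sizes 3–6 with
canonical labeling, and enrichment scoring against a degree-preserving
edge-switch null ensemble.

## The statistic

For a directed graph $G$ and a motif size $k \in \{3,\dots,6\}$, every
weakly connected induced $k$-node subgraph is assigned to its directed-graph
isomorphism class. For each class $c$ with real count $N_c$, an ensemble of
$R$ randomized graphs with the same in- and out-degree sequence gives counts
$N_c^{(1)},\dots,N_c^{(R)}$, and

$$ z_c = \frac{N_c - \bar N_c^{\mathrm{rand}}}{\sigma_c^{\mathrm{rand}}},
\qquad
p_c = \frac{1}{R}\#\{r : N_c^{(r)} \ge N_c\}. $$

A class is called significantly over-represented when $z_c > 2$ **and**
$p_c < 0.005$ with $R = 1000$ — the criterion used in published analyses of
this kind (FANMOD conventions: induced-occurrence counting, population
standard deviation, one-sided empirical p on counts, no smoothing). When
$\sigma_c^{\mathrm{rand}} = 0$ and $N_c$ equals the ensemble mean, $z_c = 0$
and the class is not significant; when $N_c$ strictly exceeds a zero-variance
ensemble, $z_c$ is flagged infinite and significance is decided by $p_c$
alone.

Named families follow the field's vocabulary: the feedforward loop
(A→B, B→C, A→C), the bifan (two regulators sharing two targets), multi-input
convergence (independent regulators converging on one target), and feedback
(any class containing a directed cycle). Larger significant classes are
additionally tagged when they contain a feedforward loop or bifan as a — not
necessarily induced — subgraph, using closed-form containment tests (an FFL
exists iff some edge is shortcut by a 2-path, i.e. $(A^2 \circ A) \ne 0$; a
bifan iff two targets share at least two regulators). The exhaustive
embedding search that justifies these shortcuts lives in the test suite as
an independent oracle.

## Projection rules

Process diagrams are not graphs; flattening them requires conventions, which
are explicit and configurable (`projection_rules()`):

* every reactant points at every product of its reaction — so associations
  point subunits at the complex, dissociations point the complex at its
  parts, and transcriptional activations point regulators at the RNA
  ("information flow follows mass flow");
* modifiers point at the reaction's **products** by default (a catalyst or
  inhibitor influences product formation); pointing them at reactants is
  supported;
* edges from inhibition reactions or inhibitory modifier roles carry an
  inhibiting sign; signs are carried through reporting but the motif stage
  deliberately treats the graph as unsigned and uncolored, matching
  plain size-$k$ motif detection;
* duplicates collapse (conflicting signs resolve to inhibiting, with a
  message), self-pairs are dropped, and the analysis restricts to the
  largest weakly connected component by default — the reconstruction of a
  curated map is expected to be one connected graph, and both the
  whole-graph and largest-component policies are available.

## Canonical labeling and enumeration

Subgraph enumeration is ESU (the algorithm behind FANMOD): each connected
$k$-subset is visited exactly once, in deterministic order given the
package's lexicographic node ordering. Classes are named by the maximum,
over all $k!$ simultaneous row/column permutations, of the row-major
bit-encoding of the adjacency matrix — at most 720 permutations at $k = 6$,
made cheap in practice by caching raw-pattern → canonical-id lookups across
the whole ensemble. Exhaustive maximization is exact (no refinement
heuristics to trust) and fast at this scale; both properties are tested
against brute-force isomorphism partitioning of all 64 labeled 3-node
digraphs (13 weakly connected classes) and against igraph's independent
motif counter.

## The null model

Randomization is the standard degree-preserving edge switch:
$Q \cdot |E|$ attempted swaps $(a{\to}b, c{\to}d) \to (a{\to}d, c{\to}b)$
per replicate, rejecting self-loops and parallel edges, with $Q = 10$.
Published analyses rarely state the switching intensity; $Q = 10$ is the
conventional default and the null-calibration experiment (below) verifies
that the ensemble mixes well enough for the criterion to be honest.
Randomization preserves the degree sequences only, not the count of mutual
edge pairs; sparse curated maps contain few mutual edges, so a
strict-mutual-preserving mode was left out. Each replicate draws from its
own RNG stream keyed on `(seed, replicate index)` (a splitmix64 generator in
the compiled core), so any replicate can be reproduced in isolation and
results are bit-identical across runs and platforms.

## What the synthetic generators emulate

The package is download-free: its test surface is generated.

* `generate_background(n, m, seed)` draws a uniform simple digraph with
  exactly `m` directed edges — the enrichment null controls degrees, so a
  uniform background suffices for benchmarking.
* `plant_motifs()` adds named motif instances on fresh (optionally
  disjoint) nodes of a background. Planted edges are unioned with the
  background, so a background edge landing inside a planted tuple can move
  that occurrence to a richer isomorphism class under induced counting;
  ground truth is therefore exact on empty backgrounds and a lower bound on
  sparse ones. Tests use empty backgrounds for exact counts and the
  enrichment criterion for sparse ones.
* `generate_synthetic_model()` builds a typed pathway model whose census
  exactly matches a declarative spec, wiring reactions by seeded draws that
  respect kind semantics (transcription produces RNA, translation converts
  RNA to protein, association forms complexes, dissociation splits them).
  Reactants preferentially reuse already-wired species and products
  preferentially recruit fresh ones, so cascades grow outward and the
  projection forms one large weak component, as curated maps do.

The map-scale preset `dc_map_spec()` fixes the composition at the published
description of a curated dendritic-cell signaling map: 249 species, 118 of
them protein-class (96 generic, 20 receptors, 2 truncated), the printed
reaction-kind breakdown (122/9/4/36/8/8/21/4 — these sum to 212; the same
source rounds the total to 213), and a 167-article literature pool with
every article citing at least one reaction. The split of the remaining 131
species among RNAs (40), complexes (60), small molecules (21) and
phenotypes (10) is not published; those values were fixed once as a
plausible structural emulation. The preset matches the map's *composition*,
not its biology: passing tests on it demonstrate that the machinery
reproduces printed census numbers through a full write → read → census
cycle and that the pipeline behaves sensibly at map scale — they say
nothing about which motifs the real curated network contains.

## Study conditions and problem sizes

The shipped analyses (under `analysis/`, re-run by `scripts/acceptance.R`)
use: the map-scale preset above for the full pipeline at sizes 3–6 with
$R = 1000$; a 200-node / 300-edge background with 30 disjoint planted
bifans for parameter recovery (size 4, default criterion), contrasted with
the bare background; and 200 replicate null draws from a 50-node / 100-edge
graph's own switching ensemble for calibration, each scored against its own
1000-network null at size 3. On one CPU the whole set completes in a few
minutes; the complete pipeline on the map-scale preset runs in well under a
minute.

## Numerical and degenerate-input choices

* Canonical ids are exact doubles (≤ 36 bits at $k = 6$).
* Empty models census to all-zero reports; graphs smaller than $k$ yield
  empty enumerations; sizes outside 3–6 are parameter errors (the upper
  bound is an argument, the implementation is size-generic).
* Graphs admitting no valid switch (e.g. a single out-star) pass through
  randomization unchanged with a message; their enrichment rows come out
  $z = 0$, $p = 1$, never significant.
* Component-size ties break toward the component containing the
  lexicographically smallest node id; enrichment rows order by $z$
  descending with canonical-id ascending tie-break; all outputs are pure
  functions of their inputs and byte-stable.

## Known limitations

* The projection collapses reaction nodes; analyses that need the bipartite
  species/reaction structure (Petri-net semantics, compartment-aware
  filtering) are out of scope.
* Motif search is unsigned and uncolored; inhibitory edges are carried as
  annotation only.
* Counting is full enumeration of induced occurrences; sampling estimators
  and overlap-restricted frequency concepts are not implemented.
* The empirical p-value has resolution $1/R$; with $R = 1000$ the smallest
  attainable p is 0, reported as such rather than smoothed.
* Real CellDesigner documents vary more than any reader can anticipate; the
  parser degrades unknown classes and reaction types to UNKNOWN rather than
  guessing, and the census reports them as such.
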