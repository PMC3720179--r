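---
title: "Protein overlap networks: model, prediction modes, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein overlap networks: model, prediction modes, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ponnet)
```

## The model

A protein overlap network (PON) is the simplest network one can build from
domain annotation alone: every protein is a node, and two proteins are joined
by an edge when they share at least one Pfam-style domain accession. Sharing
several domains still gives a single, unweighted edge; a protein with no
domain annotation is an isolated node. Because a popular domain places all of
its carrier proteins into one clique, PONs are dominated by large dense
modules connected by a few proteins whose domain combinations bridge
modules. `ponnet` never materializes edges pairwise — the network is stored
as the inverted index pair protein → domains and domain → proteins, so
cliques cost linear rather than quadratic space, and all traversals
(neighborhoods, components, breadth-first distances) run over the bipartite
incidence structure.

The working assumption behind function prediction on a PON is
guilt-by-association at the domain level: domains that co-occur with the
same partner domains tend to carry the same molecular functions, so the GO
terms seen among a protein's network neighbors are informative about the
protein itself.

### Topology statistics

`network_summary()` reports, for the main sub-graph (the largest connected
component; ties broken by lexicographically smallest member ID):

* **mean degree** — neighbors per node;
* **mean shortest path length** — averaged over ordered node pairs,
  excluding self-pairs. Paths are unweighted, so breadth-first traversal is
  used; it is exactly equivalent to Dijkstra's algorithm with unit edge
  weights, and the ordered-pair mean equals the unordered-pair mean on an
  undirected graph. For components above a few thousand nodes the mean can
  be estimated from a seeded sample of source nodes (`sample_sources`);
  the exact mode is the default and is what all tests use;
* **mean clustering coefficient** — for a node with $k_i$ neighbors of which
  $n_i$ pairs are themselves connected, $c_i = 2 n_i / (k_i (k_i - 1))$.
  Nodes of degree 0 or 1 have no defined coefficient; they are reported as
  `NA` and excluded from the mean. This convention is a choice (the
  alternative counts them as 0); it is stated here because the two
  conventions give different network means.

Component discovery, degree, clustering and path statistics are all verified
in the test suite against an independent brute-force implementation that
materializes every protein pair and hands the explicit edge list to igraph.

## Prediction modes

All modes rank candidate GO terms by their **occurrence frequency**: the
number of distinct supporting items annotated with the term. The supporting
items are *domain types* in the domain-based modes (a domain counts once no
matter how many neighbors carry it) and *neighbor proteins* in the GOA mode.

**Direct domain-based mode** (`predict_domain_direct`). Candidate domains
are those present in the query's direct neighbors. By default the query's
own domains are treated as functionally unknown — the test protocol — so
*common domains* (shared between query and neighbor) never contribute: a
term annotated only on common domains is dropped, and a term annotated on
both a common and a non-shared domain is kept but counted without the common
domain. Setting `include_shared_domains = TRUE` switches to the favorable
variant in which common domains are counted; on annotation sources where a
domain's terms are identical everywhere this variant is nearly
self-fulfilling, which is precisely why the default excludes it.

**Second-layer mode** (`predict_domain_second_layer`). Candidate domains
come from the radius-2 nodes (shortest-path distance exactly 2), minus every
domain present in the query or in any direct neighbor. One could ask for a
narrower restriction — drop only domains that co-occur with a query domain
in some protein — but on a single network the two formulations select the
same set: any protein containing both a candidate domain and a query domain
is itself a direct neighbor of the query, so a domain co-occurring with the
query anywhere is always a direct-neighbor domain. No flag is therefore
provided.

**GOA mode** (`predict_goa`). Frequencies count neighbor proteins annotated
with the term in a curated protein → GO map (GAF input). The query's own
annotations are never used. `exclude` removes whole genomes from the
neighborhood; with the query's own genome excluded this is the
leave-one-genome-out protocol — the query remains a node of the network, but
its edges into the removed genome vanish with the removed proteins.
Neighbors missing from the map contribute nothing and are not errors.

**Diversity threshold.** `min_domain_types` keeps only terms supported by at
least that many items. Raising it can only shrink candidate sets, trading
coverage for precision; the package treats `{1, 4, 16}` as the standard
grid in its own reports.

### Ties and reproducibility

All randomness flows from one integer seed through `derive_seed()`, which
hashes (seed, stream label, query ID) into independent substreams. Entries
tied on frequency are ordered by a seeded uniform key drawn per query, after
sorting term IDs so the permutation is independent of input row order. The
same seed therefore yields byte-identical output files, while different
queries still receive independent tie-breaks.

## Evaluation protocol

For a query with $k$ reference terms, the ranked list is truncated to $k$:
terms strictly above the cut-off frequency are always kept, and ties exactly
at the cut-off are filled by a seeded uniform subset (`rank_and_truncate`).
If fewer than $k$ candidates exist, all of them constitute the prediction.
GO terms are compared as opaque IDs — an exact match or a miss, no semantic
similarity. Per protein:

* **success rate** = correctly predicted / predicted (after truncation);
* **recall** = correctly predicted / reference terms;
* **top-1 / top-3** — whether the first (any of the first three) ranked
  terms hits any reference annotation; with fewer than three entries the
  available ones are judged.

A node is **predictable** when at least one (eligible) neighbor carries at
least one annotation under the mode's source. The **evaluated** set is the
proteins that are annotated (non-empty reference set) *and* receive a
non-empty prediction; **coverage** is evaluated nodes over all nodes. The
non-empty-prediction requirement matters once `min_domain_types` rises: a
protein whose candidate terms all fall below the threshold is no longer
evaluated, so coverage decreases monotonically along the threshold grid,
while a bare predictable/annotated definition would leave coverage constant
(and would force a 0/0 success rate for empty predictions). The genome-level
success rate is the unweighted (macro) mean over evaluated proteins; the
pooled (micro) rate is also reported in `glance()` output because the two
can differ when annotation counts vary widely — macro is the headline.

Reference annotations come either from the domain map itself (the union of
the query's domains' terms — the InterPro-style protocol,
`truth_source = "interpro"`) or from the curated per-protein map
(`truth_source = "goa"`).

### Randomization control

`randomize_annotations()` permutes the GO-term *sets* attached to domains
uniformly at random among the domains: the multiset of annotation sets, the
number of annotated domains, the total assignment count, and the network
topology are all conserved; only the domain-term association is destroyed.
`run_control()` repeats permutation → prediction → evaluation; the reference
sets are taken from the permuted map, i.e. a query's annotations move
together with its domains, exactly as when annotations are switched between
proteins and their domains genome-wide. Each repetition draws a fresh
permutation and a fresh tie-break substream from the master seed. The spread
of control success rates is the random baseline; a pairwise-swap Monte Carlo
chain would converge to the same uniform-permutation distribution, so the
permutation is applied directly.

## The synthetic generator

`generate_genome()` emulates the three inputs with planted structure:

* domains are partitioned into `module_structure` modules;
* each protein draws `1 + Geometric` domains (mean `domains_per_protein`,
  default 2.5 — typical of multi-domain eukaryotic proteins) from one
  module, with power-law popularity weights (`domain_popularity`, default
  0.8) so a few hub domains dominate, and with a small probability
  (`cross_module_rate`, default 0.02) of replacing a drawn domain by one
  from anywhere — the sparse long-distance connections between dense
  modules;
* every domain of a module carries the module's GO pool (`go_per_domain`
  terms, default 3), blurred by `noise_rate` (default 0.05): each
  assignment is replaced by a uniform random term with that probability;
* per-protein GOA sets are the union of the (noisy) domain terms plus a
  Poisson(`noise_rate`) number of extra protein-specific terms — functions
  a protein acquires independently of its domain content, which is what
  makes the GOA mode distinguishable from the domain mode in tests.

Topology, annotation and noise draw from independent substreams of the spec
seed, so changing the noise level never changes the network.

The defaults (200 proteins, 100 domains, 12 modules, 60-term universe) are
the package's study conditions: they give a main sub-graph holding most
proteins with mean shortest path around 4–6 and mean clustering above 0.8 —
dense modules joined by few long-range links — and a permutation-control
success rate several-fold below the planted signal, the same qualitative
separation class seen on real genome-scale PONs.

Two exact properties anchor the generator. With `noise_rate = 0` every
protein's GOA set equals the union of its domains' terms. With additionally
`cross_module_rate = 0` the modules are perfectly coherent: every term
reachable through a query's neighborhood lies in the query's own module
pool, so domain-based prediction (shared domains included) scores success
exactly 1.0 on every evaluated protein whose domains occur elsewhere — the
perfect-information limit.

### What the generator does not emulate

* Real degree distributions and the exact statistics of genome-scale PONs
  (tens of thousands of nodes, mean degree in the hundreds) — the generator
  makes no attempt to fit them.
* Partial functional coherence between adjacent modules. In the generator a
  module is either the query's own (fully redundant with its truth set) or
  unrelated, so the second-layer mode — which by construction discards all
  first-layer domains — is left with almost pure cross-module noise and
  scores near zero here, whereas on real annotation structure second-layer
  domains retain substantial signal. Second-layer results on synthetic data
  therefore say nothing quantitative about real data; the mode's counting
  logic is verified against the brute-force oracle instead.
* The GO hierarchy: terms are opaque IDs, as in the binary evaluation
  criterion.

Passing tests on synthetic genomes validate the machinery — edge semantics,
counting rules, truncation, control conservation — not real-data accuracy
figures, which depend on database snapshots this package does not ship.

## Numerical and design choices

* **Degenerate inputs.** Empty domain sets give isolated nodes; queries with
  no neighbors yield empty predictions flagged not-predictable rather than
  errors; empty reference sets exclude a protein from evaluation; a
  single-domain map is its own (only) permutation.
* **Identifier hygiene.** IDs are whitespace-stripped and case-sensitive; GO
  IDs must match `GO:` + 7 digits; duplicate protein rows union their
  domains at read time; a protein ID occurring in two genomes is prefixed
  with its genome label when networks are combined.
* **Determinism of files.** All writers emit canonically sorted rows with
  `\n` endings, so equal objects produce byte-identical files and every
  write → read → write cycle is byte-stable (including the versioned JSON
  network serialization).
* **Problem sizes.** The test suite exercises networks up to 300 nodes
  against the quadratic oracle, 20-fixture batches per counting mode, and a
  200-protein, 200-permutation control run; the acceptance script uses three
  genomes of 150–250 proteins sharing one domain vocabulary. These sizes
  were chosen to make the brute-force oracles exact and fast while keeping
  every structural regime (isolates, cliques, chains, bridges) represented.

## Known limitations

* Truth derived from the domain map is circular for the shared-domain
  variant (by design — it is the upper-bound protocol, not a benchmark).
* The macro-averaged success rate weights a one-annotation protein as much
  as a thirty-annotation one; micro averages are provided but not headline.
* No GO-hierarchy propagation, no semantic similarity, no evidence-code
  filtering beyond dropping `NOT`-qualified GAF rows.
* The InterPro-style input is a package-defined two-column TSV; converting
  real `protein2ipr` dumps into it is out of scope.
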