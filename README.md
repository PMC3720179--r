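# ponnet

Protein function prediction over **protein overlap networks** (PONs): graphs
in which every node is a protein and two proteins are connected whenever
they share at least one Pfam-style domain. Unlike interaction networks, a
PON needs nothing but domain annotation — no experiments, no homologs — yet
its neighborhoods are informative enough to transfer Gene Ontology (GO)
annotations by simple counting. `ponnet` is aimed at computational
biologists who want a reproducible, fully testable implementation of this
approach: network construction and topology statistics, four prediction
modes, the complete evaluation protocol, a permutation control, and a
synthetic genome generator so the entire pipeline runs without external
databases.

## The method

**Network.** Nodes are proteins; an edge joins proteins $i$ and $j$ iff
$D_i \cap D_j \neq \emptyset$, where $D_i$ is the set of domain accessions
of protein $i$. The network is stored as the inverted indices
protein → domains and domain → proteins (edges are implied, never listed:
popular domains create huge cliques). Topology statistics cover degree and
its distribution, connected components, breadth-first shortest paths, and
the clustering coefficient

$$c_i = \frac{2 n_i}{k_i (k_i - 1)},$$

with $k_i$ the number of neighbors of node $i$ and $n_i$ the number of
edges among them (degree-0/1 nodes are undefined and excluded from means).

**Prediction.** For a query protein, candidate GO terms are ranked by
*occurrence frequency* — the number of distinct supporting items carrying
the term:

* `predict_domain_direct()` — domain types present in direct neighbors;
  domains shared with the query are excluded from counting by default (the
  query's functions are treated as unknown), or included with
  `include_shared_domains = TRUE`;
* `predict_domain_second_layer()` — domain types found only at radius-2
  nodes, excluding everything already in the query or its neighbors;
* `predict_goa()` — neighbor proteins annotated with the term in a curated
  GAF protein→GO map, with optional leave-one-genome-out exclusion;
* composite networks from `merge_pons()` join genomes through shared domain
  accessions, enlarging neighborhoods across species.

**Evaluation.** The ranked list is truncated to the query's own annotation
count (ties at the cut-off resolved by a seeded permutation); success rate,
recall, top-1/top-3 accuracy, predictable fraction and coverage are
aggregated per genome. `run_control()` permutes the domain→GO annotation
sets genome-wide and re-runs the pipeline to give the random baseline.

## Worked example

```r
library(ponnet)

genome <- generate_genome(synthetic_genome_spec(n_proteins = 200, seed = 42))
net <- build_pon(genome)
net
#> <pon> 200 proteins, 100 domains, 1 genome(s)

network_summary(net, genome$domain2go)
#> <pon_summary> 200 proteins, 100 domains, 40 GO terms
#>   components: 6 (main sub-graph: 55 nodes)
#>   main sub-graph means: degree 12.36, path length 2.504, clustering 0.816

predict_domain_direct(net, genome$domain2go, "synthetic-P0007",
                      prediction_config(seed = 42))
#> <pon_prediction> 7 ranked terms for 1 query
#> # A tibble: 7 x 6
#>   protein_id      mode           rank go_id      frequency supporting
#>   <chr>           <chr>         <int> <chr>          <int> <list>
#> 1 synthetic-P0007 domain_direct     1 GO:0000004         4 <chr [4]>
#> 2 synthetic-P0007 domain_direct     2 GO:0000013         4 <chr [4]>
#> 3 synthetic-P0007 domain_direct     3 GO:0000032         2 <chr [2]>
#> 4 synthetic-P0007 domain_direct     4 GO:0000002         1 <chr [1]>
#> # i 3 more rows

ev <- run_genome_evaluation(net, domain2go = genome$domain2go,
                            mode = "domain_direct",
                            config = prediction_config(seed = 42))
ev
#> <pon_evaluation> 199 evaluated / 200 predictable / 200 nodes
#>   success rate 0.888 (micro 0.869), top-1 0.930, top-3 0.955
#>   recall 0.885, predictable fraction 1.000, coverage 0.995

run_control(net, genome$domain2go, n_reps = 50, seed = 42)
#> <pon_control> 50 permutations: mean success rate 0.1852 (sd 0.0298)
```

Reading the numbers: the query's top-ranked terms are each supported by four
distinct neighbor domains; across the genome, 199 of 200 proteins are both
annotated and receive a prediction, 88.8% of their truncated predictions
are correct, and the same pipeline on permuted annotations scores only
18.5% — the planted domain→function signal, not the counting machinery,
carries the accuracy. Results are tibbles throughout: `tidy(ev)` gives the
per-protein table, `glance(ev)` the one-row summary, `autoplot(ev)` the
success-rate histogram.

A command-line workflow with the same steps (subcommands `simulate`,
`build`, `props`, `predict`, `evaluate`, `control`) is available through
`pon_main()` or the wrapper script `inst/cli/pon.R`; see `?pon_main`.

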