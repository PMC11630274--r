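# trgraph

Transmission networks are the workhorse summary of genomic epidemiology:
nodes are sequenced isolates (or the patients they came from), and an edge
between two nodes asserts a plausible recent transmission link, weighted by
a pairwise relatedness value. The upstream tools that produce those values —
SNP-distance calculators, outbreak-reconstruction samplers emitting
posterior transmission probabilities, identity-by-descent (IBD) estimators
for malaria parasites — almost all print a square pairwise matrix, a format
that is bulky for sparse networks and can carry only one value per pair.

`trgraph` gives those matrices a graph-native home. It defines **trjson**, a
small JSON dialect for transmission graphs (node and edge arrays with typed,
definable attributes and a directedness flag), and provides the toolchain
around it, for epidemiologists and bioinformaticians who need to go from a
matrix to a styled, publication-ready network figure without hand-written
plotting code:

- **Conversion.** A matrix with labels `1..n` becomes a graph with one node
  per label and an edge for every pair `{i, j}` whose value `v_ij` passes a
  threshold *t* — `v_ij ≤ t` for distances (e.g. the common "≤ 50 SNPs"
  rule for recent *M. tuberculosis* transmission) or `v_ij ≥ t` for
  similarities (e.g. IBD fraction ≥ 0.2 for highly related *P. vivax*
  pairs). Asymmetric matrices convert to directed graphs with one edge per
  ordered pair, so the two directions of a pair can carry different
  transmission probabilities. The connected components of the thresholded
  graph are exactly the single-linkage clusters at that cut-off.
- **Refinement.** A small Boolean expression language
  (`"snp_distance <= 10 and region == 'Tierralta'"`) filters nodes and
  edges in place of re-running upstream tools; subgraph extraction, cluster
  labelling, and largest-cluster selection round out the tool set.
- **Annotation & export.** Sample metadata merges onto nodes or edges;
  categorical attributes with up to 12 values get a fixed qualitative
  colour palette; a seeded force-directed layout and exporters produce a
  cytoscape-dialect JSON document for web rendering, or a deterministic SVG
  / PNG with a legend.
- **Simulation.** Generators produce distance, probability and IBD matrices
  with *planted*, guaranteed-separated cluster structure plus the ground
  truth, so every pipeline stage is testable offline.

## Worked example

Simulate a 20-sample SNP-distance matrix with three planted clusters,
convert at the 50-SNP threshold, cluster, annotate and refine:

```r
library(trgraph)

sim <- simulate_distance_matrix(20, 3, seed = 101)
g <- from_pairwise_table(sim$table, conversion_spec("snp_distance", 50))
g
#> <transmission_graph: 20 nodes, 57 edges, undirected>
#>   definitions: edge/snp_distance:float

connected_components(g)
#> <component_labelling: 3 components over 20 nodes>
#>   sizes: 7, 7, 6
```

The three components are the three planted clusters: every within-cluster
distance was drawn below 20 and every between-cluster distance above 100,
so the 50-SNP cut separates them exactly. Now merge a drug-resistance
annotation, tighten the threshold without re-reading the matrix, and style:

```r
meta <- simulate_metadata(node_ids(g), list(dr = c("HR-TB", "MDR-TB")),
                          seed = 102)
g <- merge_node_metadata(g, meta)

filter_edges(g, "snp_distance <= 10")
#> <transmission_graph: 20 nodes, 26 edges, undirected>
#>   definitions: edge/snp_distance:float

style <- assign_palette(g, "dr")
style$colours
#>     HR-TB    MDR-TB
#> "#a6cee3" "#1f78b4"

layout <- compute_layout(g, seed = 42)
export_image(g, style, layout, "network.svg")          # vector + legend
export_render_document(g, style, layout, "network.json") # web renderer
write_trjson(g, "network.trjson")
```

Tightening from 50 to 10 SNPs kept 26 of the 57 links — the same graph a
direct conversion at threshold 10 would produce. A written subgraph looks
like:

```json
{
  "directed": false,
  "nodes": [
    {"id": "S001", "dr": "HR-TB"},
    {"id": "S002", "dr": "MDR-TB"}
  ],
  "edges": [
    {"source": "S001", "target": "S002", "snp_distance": 7.443967526778579}
  ],
  "definitions": [
    {"name": "snp_distance", "scope": "edge", "kind": "float"}
  ]
}
```

The same operations are available from a shell via the bundled entry point
(`system.file("cli", "tg.R", package = "trgraph")`):

```sh
Rscript tg.R convert --matrix dists.csv --attribute snp_distance \
        --threshold 50 --cmp at_most -o g.trjson
Rscript tg.R filter --edge-filter "snp_distance <= 10" g.trjson -o g10.trjson
Rscript tg.R top --n 5 g10.trjson -o cluster
Rscript tg.R export --colour-attribute dr --seed 42 cluster_1.trjson -o fig.svg
```

The trjson schema ships at `inst/schema/trjson.schema.json`; the filter
grammar reference at `inst/grammar/filter-grammar.md`.

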