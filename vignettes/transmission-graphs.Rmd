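---
title: "From pairwise relatedness matrices to transmission graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pairwise relatedness matrices to transmission graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trgraph)
```

## The model

`trgraph` treats a transmission network as a labelled graph $G = (V, E)$
where $V$ is a set of sequenced isolates and an edge asserts a putative
recent transmission link. Edges originate from a square pairwise
relatedness matrix $M$ under one of two conventions:

- **Distance** (SNP differences): small values mean related. Given a
  threshold $t$, the edge set is
  $E_t = \{\,\{i,j\} : i \ne j,\ M_{ij} \le t\,\}$. For *M. tuberculosis*
  work the conventional cut for recent transmission is $t = 50$ SNPs.
- **Similarity** (transmission probability, IBD fraction): large values
  mean related, $E_t = \{\,\{i,j\} : M_{ij} \ge t\,\}$. The conventional
  IBD cut for highly related malaria parasite pairs is $t = 0.2$; clonal
  pairs sit near 1, unrelated pairs near 0.

Both comparisons are inclusive. The field's convention of linking
isolates into "clusters" by a distance cut-off is exactly single-linkage
clustering, and single-linkage clusters are the connected components of
the thresholded graph — so `connected_components()` *is* the cluster
extractor, with no separate clustering code.

A symmetric matrix converts to an undirected graph (at most one edge per
unordered pair). An asymmetric matrix — posterior probabilities of directed
transmission, where $P(i \to j) \ne P(j \to i)$ — converts to a directed
graph with at most one edge per *ordered* pair, so a pair of isolates can
carry two edges, one per direction. A cell that is exactly 0 satisfies no
positive similarity threshold and never yields an edge; this reproduces,
with no special case, the common practice of imputing zero transmission
probability between isolates not in the same cluster, which keeps directed
graphs sparse and cluster-separated.

The graph itself is stored as **trjson**: a JSON object with a `directed`
flag, `nodes` and `edges` arrays, and an optional `definitions` array.
Nodes require a unique non-empty string `id`; edges require `source` and
`target` referencing node ids; every other key is an attribute whose value
must be a string, an integer, or a finite float — deliberately the three
kinds a delimited file can carry unambiguously. Booleans are excluded;
upstream writers must stringify them. Self-loops are rejected: matrix
diagonals are skipped on conversion, so a loop can only arise from
malformed input.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `threshold` | `conversion_spec()` | — (required) | relatedness cut, in the matrix's units (SNPs, probability, IBD fraction) |
| `comparison` | `conversion_spec()` | `at_most` | distance (`at_most`) vs similarity (`at_least`) convention; both inclusive |
| `directed` | `conversion_spec()` | `FALSE` | one edge per ordered pair when `TRUE` |
| symmetry tolerance | fixed | $10^{-9}$ (relative) | asymmetry above this in undirected mode is an error suggesting directed mode |
| `seed` | `compute_layout()` | 42 | spring-embedding seed; identical (graph, seed) gives identical coordinates |
| palette size | fixed | 12 | largest category count receiving an automatic qualitative palette |
| shape count | fixed | 6 | circle, square, triangle, diamond, hexagon, star |
| `strict` | `evaluate_filter()` | `FALSE` | missing attributes evaluate false rather than erroring |
| `resolution` | `export_image()` | 150 dpi | raster density for PNG output |

Threshold inclusivity is a deliberate choice: the 50-SNP rule is stated as
"≤ 50" in the field, and the 0.2 IBD cut is nowhere stated as strict, so
both comparisons include the boundary for symmetry. Whether the original
ecosystem treats 0.2 as strict is unknown; inclusive is this package's
documented convention, and at the boundary the difference is a measure-zero
set of pairs for continuous relatedness values.

## The filter language

Graph refinement uses Boolean expressions over attributes —
`snp_distance <= 10`, `region == 'Tierralta' and not probability < 0.5` —
with precedence `not` > `and` > `or`, parentheses, case-insensitive
keywords and case-sensitive attribute names. Two semantic choices matter:

- **Missing attributes are false**, not errors, by default. Interactive
  refinement runs over heterogeneous metadata where many nodes are only
  partially annotated; aborting on the first unannotated node would make
  the language unusable. Strict mode is an opt-in flag for pipelines that
  want the error. A consequence worth knowing: `not ghost == 1` is *true*
  on a node without `ghost`.
- **Strings never equal numbers.** Value kinds are preserved exactly as
  serialized, and `"7" == 7` being false is the price of never silently
  coercing. Ordering operators require numeric literals (enforced at parse
  time) and are false against string-valued attributes.

Filtering edges never drops the nodes left isolated: silent node loss
would corrupt cluster-size statistics computed downstream.
`drop_isolated_nodes()` is the explicit opt-in.

## What the generators emulate — and what they do not

The three matrix simulators reproduce the *structural* shape of real
inputs, with separation **enforced, not probabilistic**:

- `simulate_distance_matrix()`: symmetric, zero diagonal; within-cluster
  distances uniform on $[0, 20]$, between-cluster on $[100, 200]$ by
  default. Any threshold in $(20, 100)$ — in particular the conventional
  50 — recovers the planted clusters *exactly*. The defaults bracket 50
  because that is the cut the converted graphs will be tested at.
- `simulate_probability_matrix()`: asymmetric, diagonal zero, independent
  per-direction draws on $(0, 1)$ within clusters, exact zeros between —
  the zero-imputation convention for directed transmission probabilities.
- `simulate_ibd_matrix()`: symmetric, values in $[0, 1]$, diagonal 1;
  planted disjoint clonal pairs on $[0.9, 1]$, background on $[0, 0.1]$,
  mirroring the reported behaviour of IBD estimates on monoclonal isolates
  (clonal ≈ 1, unrelated ≈ 0). The 0.2 cut recovers the planted pairs
  exactly. Fixture scales are chosen around the tens-of-samples range
  typical of a single outbreak investigation (up to 54 isolates in the
  IBD-style fixtures).

Enforced separation is what makes recovery tests exact rather than flaky,
but it is also the generators' main departure from reality: real
SNP-distance distributions have boundary pairs near the threshold, real
posterior probabilities concentrate near 0, and real IBD backgrounds can
reach intermediate values through partial relatedness. Passing the recovery
tests therefore demonstrates that the *conversion and clustering machinery*
is correct, not that any threshold is epidemiologically right for a given
dataset — threshold choice remains a scientific judgement outside this
package's scope. The generators also make no attempt at sequence evolution,
epidemic dynamics, or sampling bias; they are structural stand-ins, not
coalescent simulations.

## Numerical and representational choices

- **Deterministic serialization.** Nodes and edges serialize in insertion
  order; object keys in fixed order (`id`/`source`/`target` first, then
  attributes sorted lexicographically in C collation); floats print as the
  shortest decimal that round-trips to the same double, with a `.0`
  appended when integral so the value re-reads as a float, not an integer.
  Identical graphs produce byte-identical documents, which makes diffs and
  caching meaningful and lets round-trip tests assert `identical()`.
- **Symmetry tolerance.** Undirected conversion requires
  $|M_{ij} - M_{ji}| \le 10^{-9} \max(1, |M_{ij}|, |M_{ji}|)$. Distance
  matrices are symmetric by construction, so anything beyond float noise
  signals a directed matrix; the error says so.
- **Missing cells** (empty, `NA`, `NaN`) are recorded as missing and never
  yield edges — they are *not* zeros, which under a similarity convention
  would wrongly assert unrelatedness.
- **Component indexing.** Components are ordered by decreasing size with
  ties broken by smallest member id (C collation), indexed from 0. This
  makes labellings reproducible across platforms and locales.
- **Layout.** Each component is laid out separately with a seeded
  Fruchterman–Reingold embedding, normalised to a unit box, and packed on
  a grid by decreasing size with a 0.5-unit gap — bounding boxes of
  disconnected components therefore never overlap, and the caller's RNG
  state is saved and restored around the embedding.
- **Palette.** The 12 colours are the fixed ColorBrewer "Paired" hex
  values, assigned in sorted value order so the mapping is independent of
  node order. Beyond 12 values the scheme is refused in favour of a single
  neutral grey plus a warning: recycling colours would silently assert
  identities that do not exist. (What the original ecosystem does beyond
  12 values is unstated; the refusal is this package's documented choice.)
- **SVG determinism.** The SVG exporter writes elements directly with
  coordinates rounded to 0.01 px, so identical inputs give byte-identical
  files; the PNG exporter draws the same primitives through the raster
  device at a caller-chosen dpi.

## Command-line surface

Each operation has a CLI verb (`convert`, `filter`, `subgraph`,
`components`, `top`, `merge-nodes`, `merge-edges`, `style`, `layout`,
`export`, `validate`, `simulate`) in a thin `Rscript` wrapper over the
package functions, so CLI output is byte-identical to library output.
Output files are written to a temporary name and renamed into place, so a
failed run never leaves a partial file. A `--config` file of `key = value`
lines supplies defaults that explicit flags override; `--seed` controls
all randomness (layout, simulation).

## Problem sizes in the checks

The bundled checks run at the scale the package targets: conversion is
verified against brute-force pair enumeration on 100 random matrices of
5–30 samples (both conventions, both directedness modes); cluster and
clonal-pair recovery on 50 planted fixtures each (10–54 samples); the
filter language against an independent recursive evaluator on 500 random
expression trees of depth ≤ 3; serialization on 100 random graphs; and
the full simulate → convert → filter → top-5 → style → layout → export
pipeline on a 40-sample directed fixture. These sizes keep the whole suite
in the tens of seconds on a single core while exercising every code path
at desk scale — which is also the package's intended scale: graphs are
held in memory, and there is no streaming parser for networks larger than
memory.

## Known limitations

- The trjson dialect's `directed` and `definitions` key names are this
  package's canonical choice; files from other transmission-graph tools
  may use different conventions, and interoperability is best-effort.
- No centrality metrics, transmission-chain reconstruction, or temporal
  inference: the package manipulates and renders graphs that upstream
  inference produced; it does not infer who infected whom.
- The filter language deliberately omits arithmetic between attributes,
  regular expressions and set membership; string matching is exact and
  case-sensitive.
- Rendering targets static figures and a web-renderer dialect; there is no
  interactive viewer in this package.
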