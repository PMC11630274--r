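Package: trgraph
Title: Build, Refine and Export Transmission Graphs from Pairwise Relatedness Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with transmission networks in genomic
    epidemiology. Defines 'trjson', a JSON dialect for transmission graphs
    with typed node and edge attributes, and provides converters from
    pairwise relatedness matrices (SNP distances, directed transmission
    probabilities, identity-by-descent fractions) and long-format edge
    tables into graphs under distance or similarity thresholds. Graphs can
    be refined with a small Boolean attribute-expression language, merged
    with sample metadata, decomposed into single-linkage clusters, styled
    with a qualitative palette, laid out deterministically, and exported to
    a web-renderer element dialect or to static SVG/PNG figures with
    legends. A synthetic-data module generates matrices with planted
    cluster structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
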