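Package: commview
Title: Hierarchical Community Detection and Multi-Resolution Views of Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a divisive hierarchy of non-overlapping communities on
    weighted protein-protein interaction networks by repeated application of
    the Louvain modularity heuristic, labels the resulting community tree
    with pre/post-order intervals for constant-time ancestry queries,
    precomputes a community-relation index recording which disjoint
    communities are connected by underlying network edges, and exposes a
    zoom-in/zoom-out view algebra for navigating the network at multiple
    resolutions with meta-nodes (communities) and atomic nodes (proteins).
    Includes readers and writers for tab-separated edge lists and protein
    identifier mapping tables, community and map-tree exporters (TSV, JSON,
    Newick), a hierarchical planted-partition generator for benchmarking,
    and a headless command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
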