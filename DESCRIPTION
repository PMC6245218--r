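Package: molcollab
Title: Collaborator Recommendation from Molecule-Publication-Author Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an in-memory heterogeneous multilayer network linking a
    molecular interaction layer, a bibliographic publication layer and an
    author layer, and recommends potential collaborators for a query
    molecule. Ranking methods include three publication-count measures
    (non-normalized, normalized, and hypergeometric enrichment) and a
    weighted PageRank over the query-specific coauthorship subnetwork, with
    a collaboration-strength weight that discounts prolific authors. Also
    provides the coauthor-proximity validation analysis (2x2 contingency
    table, odds ratio, exact test), rank-comparison utilities, deterministic
    synthetic-network generators with planted expert authors, and plain-text
    ingestion/export of all layers.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
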