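Package: obokit
Title: Semantic Query Functions for OBO Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Loads ontologies in OBO 1.2 flat-file format into typed
    directed graphs (is_a hierarchy plus named relation edges under a
    virtual root) and answers ontology-semantic queries: field-restricted
    substring search, mapping of classes to ancestors at a fixed level or
    down to a bounded number of clusters, rollup of anatomical entities to
    key classes such as organs along a restricted relation set,
    level-synchronous breadth-first search against stored class sets, and
    partitioning of a staged anatomy ontology into stage-linked (concrete)
    and stage-free (generic) classes.  Ships a flat-file store for named
    class lists, a REST-style resource router with an HTTP server and a
    lazy-loading client, a command-line interface, and generators for the
    small fixture ontologies used throughout the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    httpuv,
    curl,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
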