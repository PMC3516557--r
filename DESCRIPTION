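Package: painmap
Title: Cross-Species Systems Mapping of Nociception Screen Hits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a cross-species "pain systems network" from a
    genome-wide functional screen: projects fly thermal-nociception hits
    onto mammalian orthologs across several prediction sources, expands
    the hit set by first-degree physical binding partners, runs
    hypergeometric over-representation tests against KEGG-, C2- and
    GO-style gene-set collections with collection-specific significance
    policies and ontology-aware term pruning, assembles a bipartite
    functional-class/gene network, and validates the network's overlap
    with known pain annotations against a size-matched random-gene-list
    null. Ships a synthetic-data generator that emulates the statistical
    structure of the real inputs (multi-source orthology with mixed
    mapping topologies, sparse binary interactions, planted gene-set
    enrichment, planted annotation overlap) so the whole pipeline is
    testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
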