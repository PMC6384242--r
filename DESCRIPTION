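Package: immunoscreen
Title: Immune Health Endpoint Gene Sets, Overlap Analysis and Chemical
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles gene sets for four immune health endpoints
    (hypersensitivity, autoimmunity, resistance to infection, resistance
    to cancer) from curated disease-gene associations with MeSH hierarchy
    expansion, cross-references them against Gene Ontology biological
    processes, computes the full Venn partition and bipartite
    gene-endpoint network, refines candidates to secreted proteins via
    UniProt-style annotation, ranks candidate biomarkers, and screens
    chemicals or food substances by mapping their top curated interacting
    genes onto the endpoint sets. Ships a synthetic-fixture generator
    that emulates all input dialects with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
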