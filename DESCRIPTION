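Package: retroplan
Title: Template-Based Retrosynthetic Route Planning with Feasibility
    Classifiers and k-Best Hyperpath Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans synthetic routes for a target compound by applying a
    curated library of named-reaction retro-templates (SMIRKS), scoring each
    candidate disconnection with a per-template feasibility classifier,
    growing a reaction network toward purchasable building blocks with one of
    four expansion heuristics, and extracting the k lowest-cost diversified
    routes from the resulting AND-OR synthesis graph with a vectorized
    Dijkstra search. Route costs combine building-block prices with reaction
    yields. Includes seeded generators for synthetic networks, training
    corpora and database fixtures, plus readers and writers for building-block
    and single-step reaction databases. Molecular primitives (canonical
    SMILES, substructure matching, SMIRKS application, circular fingerprints)
    are provided by RDKit through a persistent Python worker process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    processx,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH.
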