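Package: scbgraph
Title: Semantic Knowledge Graphs for Systems Chemical Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries an OWL ontology-backed knowledge graph for
    chemogenomics and systems chemical biology. Provides a class/property
    schema covering small molecules, drugs, proteins, bioassays, diseases,
    side effects, pathways, literature and a 61-class chemical-protein
    interaction hierarchy; an annotation pipeline that unifies heterogeneous
    source tables into one semantic graph with identifier resolution and
    cross-reference provenance; forward-chaining RDFS-style materialization;
    a SPARQL-subset query engine with parameterized query templates for
    drug-target search, ligand filtering, disease expansion and shared-drug
    target ranking; bounded simple-path mining over the entity graph; and a
    deterministic synthetic fixture generator with a ground-truth manifest.
    Graphs serialize to Turtle and RDF/XML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    xml2,
    yaml,
    jsonlite,
    igraph,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
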