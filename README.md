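# scbgraph

Semantic knowledge graphs for systems chemical biology and chemogenomics.

Chemogenomics data — which compounds bind, activate, inhibit or regulate
which protein targets, with what assay evidence, and how drugs relate to
diseases and side effects — is scattered across databases that each use
their own identifiers and schemas. Querying them jointly normally means
writing queries that name every source explicitly and reconcile
identifiers by hand. `scbgraph` takes the ontology-annotation approach
instead: heterogeneous source tables are resolved to primary identifiers,
annotated as instances of one OWL ontology, enriched by rule-based
reasoning, and then queried through source-independent SPARQL patterns.
It is aimed at cheminformaticians and bioinformaticians who want a small,
fully offline, reproducible toolkit for building and mining such graphs.

## What it provides

* **Ontology schema** — nine primary classes (`SmallMolecule`, `Drug`,
  `Protein`, `BioAssay`, `Disease`, `SideEffect`, `Literature`, `Pathway`,
  `Interaction`), five `Interaction` subclasses, and a 61-class
  chemogenomic interaction hierarchy under `ChemicalProteinInteraction`,
  split into *chemical-regulates-protein* (binding and receptor
  pharmacology, activity/expression regulation, post-translational
  modification) and *protein-regulates-chemical* (metabolism, transport,
  catalysis) branches, plus utility classes for structures,
  cross-references, assay outcomes and physical properties. Serializes to
  Turtle and RDF/XML.
* **Entity resolution** — compounds resolve to PubChem CIDs (explicit
  cross-reference, then offline InChI lookup, then a deterministic
  surrogate CID from a reserved negative namespace); drugs, proteins and
  side effects use DrugBank IDs, UniProt entry names and UMLS IDs;
  free-text disease mentions map to Disease Ontology IDs by exact and
  token-set similarity matching.
* **Annotation** — interactions become first-class nodes with
  `ro:has_participant` links, `BioAssay` evidence carrying
  (measurement, relation, value, unit) outcome quadruples,
  `UnificationXref` provenance on every entity and interaction, and
  `PublicationXref` article references.
* **Reasoning** — forward-chaining materialization of subclass typing,
  inverse properties, transitive closure and domain/range typing, with
  asserted and inferred triples kept distinguishable.
* **Querying** — a SPARQL subset engine (basic graph patterns, `FILTER`,
  `UNION`, `OPTIONAL`, `DISTINCT`, `GROUP BY`/`COUNT`, `ORDER BY`) and
  templates for drug-target search, assay evidence retrieval,
  agonist/antagonist ligand filtering by molecular weight, disease-gene
  search with hierarchy expansion, and ranking targets of disease-linked
  drugs by shared drug counts.
* **Graph mining** — contraction of the RDF graph to a labeled entity
  network (with GO-term-sharing and precomputed structural-similarity
  edges) and exhaustive bounded simple-path enumeration between entities.
* **Fixtures** — a seeded generator for synthetic source tables shaped
  like PubChem/ChEMBL/UniProt/DrugBank/BindingDB/CTD/SIDER dumps, with a
  brute-force ground-truth manifest.

## Worked example

The canonical micro-example is the thiazolidinedione drug Troglitazone
(PubChem CID 5591, ChEBI 9753) binding the nuclear receptor PPARG, tested
in one bioassay with a published reference:

```r
library(scbgraph)
sc <- build_schema()
glance(sc)
#>   n_classes n_properties n_primary n_interaction_subclasses n_chemogenomic
#> 1        83           26         9                        5             61

gm <- annotate_worked_example() |> materialize(sc)
glance(gm)
#>   n_triples n_asserted n_inferred n_instances n_predicates
#> 1       105         83         22          21           25

drug_targets(gm, "Troglitazone")
#>   target
#> 1 PPARG

interaction_evidence(gm, "Troglitazone", "PPARG")
#>   description                          measurement relation value unit  title
#> 1 synthetic placeholder binding assay…        IC50        =   200   nm  synth…
```

The 83 asserted triples grow to 105 under reasoning: the binding
interaction acquires its `ChemicalProteinInteraction` and `Interaction`
supertypes (which is what lets the source-independent drug-target query
find it), participants gain inverse `participates_in` edges, and
domain/range axioms type the helper nodes. The evidence row carries the
assay outcome quadruple (IC50 = 200 nm; placeholder values) and the
article title found through an `OPTIONAL` clause.

Path mining on a small network around a benzimidazole-like compound and
the hERG channel (KCNH2) recovers three kinds of indirect association —
via structurally similar compounds that bind the target, via a second
target sharing a ligand, and via GO-term sharing between targets:

```r
px <- path_mining_example()
find_paths(px$entity_graph, px$query_compound, px$target, max_len = 4)
#>   length labels
#> 1      2 similar_to -> c2b2r:Binding        (x3)
#> 2      2 c2b2r:Binding -> shares_go_term
#> 3      3 c2b2r:Binding -> c2b2r:Binding -> c2b2r:Binding
```

A thin CLI over the same functions lives at `inst/cli/scb.R`
(`build-ontology`, `fixtures`, `annotate`, `reason`, `query`, `sparql`,
`paths`).

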