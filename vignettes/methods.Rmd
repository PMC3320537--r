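---
title: "Methods: ontology, annotation, reasoning and mining in scbgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology, annotation, reasoning and mining in scbgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbgraph)
```

## The data model

`scbgraph` models systems chemical biology data as an RDF graph typed by
a compact OWL ontology. The physical entities (small molecules, drugs,
proteins) sit under `PhysicalEntity`; diseases, side effects and pathways
are atomic top-level classes (`Pathway` deliberately carries nothing but
a name — pathway internals are out of scope); `BioAssay` and `Literature`
sit under `Evidence`. The design's central commitment is that *relations
with context are classes, not predicates*: an interaction between
entities is a first-class node, typed by one of five `Interaction`
subclasses, that carries its participants (`ro:has_participant` /
`ro:participates_in`), its experimental evidence, and its provenance.
This is what makes source-independent querying work: a query can ask for
"any chemical-protein interaction" without knowing which database
reported it or what shape that database had.

Chemical-protein interactions get a finer vocabulary: a hierarchy of 61
named classes under `ChemicalProteinInteraction`, divided into a
*chemical-regulates-protein* branch (binding with receptor-pharmacology
subtypes such as agonist/antagonist/partial-agonist activity and channel
block/opening; activity regulation; expression regulation;
post-translational modification pairs; stability, cleavage, degradation,
secretion, localization and related effects) and a
*protein-regulates-chemical* branch (metabolism with oxidation,
reduction, hydrolysis and conjugation subtypes; transport with
import/export/efflux; catalysis, synthesis, degradation and related
actions). The count of 61 is a fixed structural contract of the schema,
enumerated in one versioned table (`R/schema-terms.R`) and checked by
tests; the composition itself is this package's canonical choice, modeled
on the CTD interaction-type vocabulary plus receptor pharmacology terms,
since no finer-grained external standard is imported at build time.
External mappings (BioPAX, GO, DO) are stored as annotation literals, not
imports, so building is fully offline and deterministic.

Utility classes carry payloads that need more than one field:
`ChemicalStructure` (format + representation, so one molecule can bear a
SMILES and an InChI simultaneously), `BioAssayOutcome` (measurement,
relation, value, unit — e.g. IC50 = 200 nm), `PhysicalProperty`
(molecular weight), and the provenance pair `UnificationXref` (this node
equals record DB/ID elsewhere) and `PublicationXref` (this assertion was
reported in that article).

## Identifier resolution

Every entity kind has one primary identifier namespace: PubChem CID for
compounds, DrugBank ID for drugs, UniProt entry name for proteins
(matched case-insensitively), UMLS ID for side effects, Disease Ontology
ID for diseases, and the plain name for pathways. URIs are minted
deterministically from (kind, primary id), so records from different
sources that resolve to the same identifier become one node and their
cross-references union automatically — merging is the only possible
outcome, never splitting.

Compound resolution has three branches, in fixed order: an explicit
PubChem cross-reference wins; otherwise the record's InChI is looked up
in an offline InChI-to-CID table supplied as input (a pluggable stand-in
for a live PubChem search, chosen so runs are reproducible and
network-free); otherwise a surrogate CID is minted. Surrogates are
negative integers — a namespace disjoint from real CIDs by construction —
assigned in first-seen order within a resolution context and serialized
as `compoundF<n>`. Conflicting PubChem cross-references on one record are
an error rather than a silent choice.

Disease mentions arrive as free text. Matching proceeds: exact DOID;
case/punctuation-normalized exact match against labels and synonyms;
token-set Jaccard similarity with a default threshold of 0.8, ties broken
by the lexicographically smallest DOID. The threshold is a tunable
(`resolution_context(disease_threshold = …)`); 0.8 keeps one-word
mismatches in short medical phrases out while accepting reordered or
lightly inflected forms. Terms with no candidate above threshold are
excluded and logged, not errors: a mapping pipeline should survive messy
vocabularies.

## Annotation and provenance

`annotate()` consumes per-source tables plus a column-mapping
declaration (YAML or list) that assigns each column either an ontology
term or a structural role (cross-reference with database name,
participant of a given kind, interaction-class column with a value map,
outcome field, publication reference, structure representation). Entity
records become typed instances — exactly one asserted `rdf:type`, the
most specific mapped class; broader types appear only through reasoning,
keeping the asserted/inferred separation testable. Interaction records
become interaction nodes whose URI encodes (source, record id), so
parallel records of the same chemical-protein pair from different
databases deliberately remain distinct nodes sharing participants: the
multiplicity of reporting is information, and each node carries a
`UnificationXref` naming its source. Records referencing unresolvable
participants are skipped with a logged reason. Publication references
attach to the bioassay node, mirroring how evidence queries retrieve
them with an `OPTIONAL` clause.

Helper nodes (cross-references, outcomes, structures, physical
properties, assays) use skolemized URIs — a short hash of the parent URI
plus content — rather than blank nodes. Identical content therefore
collapses to one node under set-union semantics, deduplication is a
`distinct` over triples, and graph comparison in tests is exact. Numeric
fields that fail to parse are kept as string-typed literals: they remain
visible as annotation but are transparently excluded from numeric
filters, which only see `xsd:double` values. Units are stored verbatim
with no nm/um conversion; numeric comparisons are meaningful within one
unit, and no conversion policy is invented.

## Reasoning

`materialize()` computes the least fixpoint of a fixed, closed rule set:
type propagation along the subclass hierarchy, subproperty propagation,
inverse completion, transitive closure of transitive properties (the
disease hierarchy's `subDiseaseOf`), and domain/range typing. This
RDFS-plus profile is exactly what the shipped queries need — finding
leaf-typed interactions through their superclasses, traversing
participation in either direction, expanding disease subtrees — and
nothing more: no consistency checking, property chains or cardinality
reasoning. The engine is semi-naive (each round joins only newly derived
triples), is idempotent and monotone by construction, and tags inferred
triples with an `inferred` origin so exports can include or exclude them
(`write_graph(..., include_inferred = FALSE)`). Instances typed by
classes outside the schema produce a warning and are left un-propagated.
Correctness is checked against an independent naive-iteration oracle on
random graphs (20 seeds, 20–50 nodes) in both the test suite and the
acceptance script.

## Querying

The SPARQL engine supports precisely the constructs the shipped query
patterns use: basic graph patterns with `;`/`,` abbreviations and
bracketed blank-node property lists, `FILTER` expressions
(comparisons, boolean connectives), `UNION`, `OPTIONAL`, `DISTINCT`,
`GROUP BY` with `COUNT`/`COUNT(DISTINCT)` aggregates, and `ORDER BY`.
`FROM` clauses are accepted and ignored — there is exactly one local
graph. Anything outside the subset raises a typed unsupported-feature
error rather than silently mis-evaluating, and syntax errors report the
character position. Evaluation is by successive tibble joins (left joins
for `OPTIONAL`, row-binding for `UNION`), with group filters applied at
group scope.

The templates encode the toolkit's case-study patterns: `drug_targets`
(all proteins in any chemical-protein interaction with a labeled
chemical), per-source variants that constrain interaction provenance
(used to test the integration-equivalence property: the ontology-level
query equals the union of per-source queries), `interaction_evidence`
(assay rows with outcome quadruples and optional article titles),
`ligands_by_activity` (compounds of a given activity class with
molecular weight *strictly* below a cutoff — a weight of exactly 500
is excluded by a `< 500` filter), `disease_genes` with optional
descendant expansion, and `rank_targets` (targets of disease-linked
drugs grouped and counted by distinct shared drugs, sorted by
descending count with alphabetical tie-break). Ranking expands the
disease to its descendants by default, matching how a coarse disease
term aggregates its subtypes' drug links. Outcome-value filters in
hand-written queries compare lexical numbers; whether bounded
measurements (relation ≤ or ≥) should enter such filters is left to the
query author — the outcome relation is returned alongside the value
precisely so callers can decide.

## Graph mining

`build_entity_graph()` contracts each interaction node to a labeled edge
between its two participants (cliques for more participants), labeled by
the interaction's most specific asserted class; proteins sharing at
least one GO annotation gain a `shares_go_term` edge, and disease-gene
links become edges too. Literals and helper nodes are excluded. Edges
are treated as undirected for path finding — these are associations, not
causal flows. Structural-similarity edges are overlaid from precomputed
score pairs (`add_similarity_edges`, default threshold 0.85, scores
validated to [0, 1]); computing fingerprints or Tanimoto scores is
deliberately out of scope, keeping chemistry perception outside the
core. `find_paths()` enumerates all simple paths up to `max_len` edges
(default 4 — the interesting association motifs are length 2–3, and 4
gives headroom at tractable cost), keeping the label of every traversed
edge so parallel edges with different labels yield distinct paths,
ordered by length then lexicographic node and label sequence. Exhaustive
correctness is oracle-checked against an independent DFS enumeration.

## The fixture generator

`generate_fixtures()` emulates the *shape* of the public chemogenomics
ecosystem, not its scale or chemistry: a PubChem-like hub that is
authoritative for CIDs; a ChEMBL-like compound table without CIDs whose
30% InChI overlap with the hub forces cross-source merges and whose
orphan rows (default 10%) force surrogate minting; UniProt-like proteins
with GO annotations; DrugBank-like drugs and drug-target actions;
BindingDB-like assayed interactions with outcome quadruples (measurement
drawn from EC50/IC50/Ki/Kd, units um/nm, relations =/</>) and partial
publication coverage; a CTD-like interaction table with a different
column vocabulary (so the mapping layer is genuinely exercised); a
SIDER-like drug-disease table whose free-text mentions are drawn from
Disease Ontology labels and synonyms; and a fixed mini disease tree
(a hepatobiliary subtree carrying the "liver toxicity" synonym and a
heart-disease subtree carrying "heart attack") padded with synthetic
diseases. Everything derives from one seed and is byte-identical across
runs. A ground-truth manifest — drug-target sets, per-source sets,
evidence counts, disease-gene sets, rankings — is recomputed from the
emitted tables by brute-force counting, independent of the annotation
pipeline, and the suite re-derives parts of it a second time with plain
loops.

What passing tests on these fixtures shows is structural correctness:
resolution branch coverage, mapping-driven annotation, reasoning,
query semantics and mining agree with independent oracles on data shaped
like the real sources. What they cannot show is robustness to the real
sources' messiness — genuine InChI collisions, inconsistent casing and
salt forms, free text far from any ontology label — nor anything about
real biology or chemistry: fixture values are placeholders, and the
worked Troglitazone-PPARG example fixes real identifiers (CID 5591,
ChEBI 9753, PPARG) but synthetic measurements.

## Problem sizes and numerical choices

The test suite and acceptance script use: a 200-compound two-source
fixture (150 interactions) for the integration-equivalence property; 20
random instance graphs of 20–50 nodes for the reasoning oracle; 20
random 30-node labeled multigraphs (45 edge draws) for the path oracle;
20 random bipartite fixtures (8 drugs x 6 targets) for ranking; and the
fixed micro-fixtures for the worked example and motif recovery. These
sizes make every oracle comparison exact and exhaustive while keeping a
full run inside a few minutes on one core.

Other fixed numerical choices: surrogate CIDs are assigned -1, -2, … in
first-need order; disease fuzzy-match ties prefer the smallest DOID;
ranking ties are alphabetical; path results order by (length, node
sequence, label sequence); skolem hashes take the first 16 hex digits of
an md5; Turtle and RDF/XML round trips compare graphs as canonical
triple sets (with signature-based blank-node matching, though the
package itself never emits blank nodes). Degenerate inputs are defined
to do the obvious: empty record lists produce empty graphs, unknown
labels produce empty result sets, an empty cross-reference list leaves a
graph unchanged, and endpoint-missing path queries are lookup errors.

## Known limitations

* The SPARQL subset is intentionally small; notably `LIMIT`, `BIND`,
  property paths and regular-expression filters are rejected rather than
  implemented.
* Reasoning is RDFS-plus; OWL-DL features (restrictions, cardinality,
  consistency checking) are out of scope, so the materialized graph is a
  sound but deliberately incomplete approximation of a description-logic
  reasoner on richer ontologies.
* No unit conversion between nm and um in outcome values; filters are
  per-unit.
* Similarity is an input; no structure standardization, fingerprinting
  or InChI computation is performed.
* Batch annotation only; there is no incremental update of an existing
  graph.
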