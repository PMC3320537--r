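# Canonical term tables for the ontology schema.
#
# The chemogenomic interaction hierarchy is fixed here as one versioned
# table: two branch roots (how chemicals act on proteins, and how proteins
# act on chemicals) populated with action terms modeled on the CTD
# interaction-type vocabulary plus receptor pharmacology terms. Counted as
# all named classes strictly below ChemicalProteinInteraction the table has
# exactly 61 entries, and tests enumerate it.

chemogenomic_class_table <- function() {
  crp <- "ChemicalRegulatesProtein"
  prc <- "ProteinRegulatesChemical"
  tibble::tribble(
    ~name, ~parent,
    crp, "ChemicalProteinInteraction",
    prc, "ChemicalProteinInteraction",

    # -- chemical regulates protein ------------------------------------
    "Binding", crp,
    "CovalentBinding", "Binding",
    "ReceptorAgonistActivity", "Binding",
    "ReceptorAntagonistActivity", "Binding",
    "ReceptorPartialAgonistActivity", "Binding",
    "ReceptorInverseAgonistActivity", "Binding",
    "ChannelBlockerActivity", "Binding",
    "ChannelOpenerActivity", "Binding",

    "ActivityRegulation", crp,
    "Activation", "ActivityRegulation",
    "Inhibition", "ActivityRegulation",
    "CompetitiveInhibition", "Inhibition",
    "AllostericModulation", "ActivityRegulation",

    "ExpressionRegulation", crp,
    "ExpressionIncrease", "ExpressionRegulation",
    "ExpressionDecrease", "ExpressionRegulation",

    "PostModificationRegulation", crp,
    "PhosphorylationIncrease", "PostModificationRegulation",
    "PhosphorylationDecrease", "PostModificationRegulation",
    "MethylationIncrease", "PostModificationRegulation",
    "MethylationDecrease", "PostModificationRegulation",
    "AcetylationIncrease", "PostModificationRegulation",
    "AcetylationDecrease", "PostModificationRegulation",
    "UbiquitinationIncrease", "PostModificationRegulation",
    "UbiquitinationDecrease", "PostModificationRegulation",
    "GlycosylationIncrease", "PostModificationRegulation",
    "GlycosylationDecrease", "PostModificationRegulation",

    "StabilityIncrease", crp,
    "StabilityDecrease", crp,
    "CleavageIncrease", crp,
    "CleavageDecrease", crp,
    "DegradationIncrease", crp,
    "DegradationDecrease", crp,
    "SecretionIncrease", crp,
    "SecretionDecrease", crp,
    "LocalizationChange", crp,
    "FoldingChange", crp,
    "Chelation", crp,
    "Intercalation", crp,
    "MutagenesisResponse", crp,
    "CofactorActivity", crp,

    # -- protein regulates chemical ------------------------------------
    "ChemicalMetabolism", prc,
    "Oxidation", "ChemicalMetabolism",
    "Reduction", "ChemicalMetabolism",
    "Hydrolysis", "ChemicalMetabolism",
    "Glucuronidation", "ChemicalMetabolism",
    "Sulfation", "ChemicalMetabolism",
    "Demethylation", "ChemicalMetabolism",

    "ChemicalTransport", prc,
    "ChemicalImport", "ChemicalTransport",
    "ChemicalExport", "ChemicalTransport",
    "ChemicalEfflux", "ChemicalTransport",

    "ChemicalCatalysis", prc,
    "ChemicalSynthesis", prc,
    "ChemicalDegradation", prc,
    "ChemicalCleavage", prc,
    "ChemicalSequestration", prc,
    "ChemicalStabilization", prc,
    "ChemicalModification", prc
  )
}

primary_class_names <- function() {
  c("SmallMolecule", "Drug", "Protein", "BioAssay", "Disease",
    "SideEffect", "Literature", "Pathway", "Interaction")
}

interaction_subclass_names <- function() {
  c("DrugInducedSideEffect", "DrugTreatment", "DrugDrugInteraction",
    "ProteinProteinInteraction", "ChemicalProteinInteraction")
}

utility_class_names <- function() {
  c("ChemicalStructure", "UnificationXref", "PublicationXref",
    "BioAssayOutcome", "PhysicalProperty")
}

# Full class table: name, parent (NA = top level), definition, external mapping.
base_class_table <- function() {
  top <- tibble::tribble(
    ~name, ~parent, ~definition, ~external,
    "PhysicalEntity", NA, "A physical object such as a molecule or protein.", "biopax:PhysicalEntity",
    "SmallMolecule", "PhysicalEntity", "A small bioactive molecule.", "biopax:SmallMolecule",
    "Drug", "PhysicalEntity", "A chemical used in treatment, cure, prevention or diagnosis of disease.", NA,
    "Protein", "PhysicalEntity", "A physical entity consisting of a sequence of amino acids.", "biopax:Protein",
    "Evidence", NA, "Support for an assertion, such as an experiment or an article.", "biopax:Evidence",
    "BioAssay", "Evidence", "An experiment measuring the effect of a substance on a target, cell or organism.", NA,
    "Literature", "Evidence", "A scientific article.", NA,
    "Disease", NA, "A condition causing pain, dysfunction, distress or social problems.", "doid:4",
    "SideEffect", NA, "An undesired effect of a medicine.", NA,
    "Pathway", NA, "A set or series of biological interactions (treated as a black box).", "biopax:Pathway",
    "Interaction", NA, "A relation between entities carrying its own context and evidence.", "biopax:Interaction",
    "DrugInducedSideEffect", "Interaction", "A drug interaction that results in a side effect.", NA,
    "DrugTreatment", "Interaction", "The use of a drug to treat a disease.", NA,
    "DrugDrugInteraction", "Interaction", "A drug affecting the activity of another drug.", NA,
    "ProteinProteinInteraction", "Interaction", "Two or more proteins binding together.", NA,
    "ChemicalProteinInteraction", "Interaction", "A genomic or biochemical response of a protein to a chemical.", NA,
    "UtilityClass", NA, "Helper classes that present primary classes.", "biopax:UtilityClass",
    "ChemicalStructure", "UtilityClass", "A structure representation (format plus data) borne by a small molecule.", "biopax:ChemicalStructure",
    "UnificationXref", "UtilityClass", "A reference to an external record with the same biological identity.", "biopax:UnificationXref",
    "PublicationXref", "UtilityClass", "A reference to the article reporting an assertion.", "biopax:PublicationXref",
    "BioAssayOutcome", "UtilityClass", "The measurement, relation, value and unit of an assay result.", NA,
    "PhysicalProperty", "UtilityClass", "A physical property, such as molecular weight, borne by an entity.", NA
  )
  chem <- chemogenomic_class_table()
  chem$definition <- paste0("Chemogenomic interaction type: ", chem$name, ".")
  chem$external <- NA_character_
  dplyr::bind_rows(top, chem)
}

# Property table. Prefixed names; expanded against the namespace table.
base_property_table <- function() {
  tibble::tribble(
    ~name, ~kind, ~domain, ~range, ~inverse, ~transitive,
    "ro:participates_in", "object", NA, "Interaction", "ro:has_participant", FALSE,
    "ro:has_participant", "object", "Interaction", NA, "ro:participates_in", FALSE,
    "bp:evidence", "object", "Interaction", "Evidence", NA, FALSE,
    "bp:xref", "object", NA, NA, NA, FALSE,
    "bp:structure", "object", "SmallMolecule", "ChemicalStructure", NA, FALSE,
    "c2b2r:hasOutcome", "object", "BioAssay", "BioAssayOutcome", NA, FALSE,
    "c2b2r:hasPhysicalProperty", "object", NA, "PhysicalProperty", NA, FALSE,
    "c2b2r:has_disease_gene", "object", "Disease", "Protein", NA, FALSE,
    "c2b2r:has_go_annotation", "object", "Protein", NA, NA, FALSE,
    "c2b2r:subDiseaseOf", "object", "Disease", "Disease", NA, TRUE,
    "rdfs:label", "data", NA, "xsd:string", NA, FALSE,
    "c2b2r:CID", "data", "SmallMolecule", "xsd:integer", NA, FALSE,
    "bp:structureFormat", "data", "ChemicalStructure", "xsd:string", NA, FALSE,
    "bp:structureData", "data", "ChemicalStructure", "xsd:string", NA, FALSE,
    "c2b2r:chemicalFormula", "data", "SmallMolecule", "xsd:string", NA, FALSE,
    "c2b2r:molecularWeight", "data", "PhysicalProperty", "xsd:double", NA, FALSE,
    "c2b2r:measurement", "data", "BioAssayOutcome", "xsd:string", NA, FALSE,
    "c2b2r:relation", "data", "BioAssayOutcome", "xsd:string", NA, FALSE,
    "c2b2r:value", "data", "BioAssayOutcome", "xsd:double", NA, FALSE,
    "c2b2r:unit", "data", "BioAssayOutcome", "xsd:string", NA, FALSE,
    "c2b2r:description", "data", "BioAssay", "xsd:string", NA, FALSE,
    "c2b2r:title", "data", "PublicationXref", "xsd:string", NA, FALSE,
    "c2b2r:DB", "data", "UtilityClass", "xsd:string", NA, FALSE,
    "c2b2r:ID", "data", "UtilityClass", "xsd:string", NA, FALSE,
    "c2b2r:comments", "data", "UtilityClass", "xsd:string", NA, FALSE,
    "c2b2r:DOID", "data", "Disease", "xsd:string", NA, FALSE
  )
}
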