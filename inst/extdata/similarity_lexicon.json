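{
  "comment": "Hand-built deterministic synset taxonomy used by the packaged similarity provider. Each synset has member words, a gloss (Lesk), a hypernym link (Path/Lin) and an occurrence count (Lin information content). Synthetic fixture; not derived from WordNet data.",
  "synsets": [
    {"id": "entity", "hypernym": null, "words": ["entity"], "count": 500,
     "gloss": "that which is perceived to have its own distinct existence"},
    {"id": "physical_entity", "hypernym": "entity", "words": [], "count": 50,
     "gloss": "an entity that has physical existence"},
    {"id": "object", "hypernym": "physical_entity", "words": ["object"], "count": 40,
     "gloss": "a tangible and visible entity"},
    {"id": "location", "hypernym": "object", "words": ["location"], "count": 20,
     "gloss": "a point or extent in space"},
    {"id": "region", "hypernym": "location", "words": ["region", "area"], "count": 15,
     "gloss": "a large extent of space or surface"},
    {"id": "site", "hypernym": "region", "words": ["site", "place", "position"], "count": 30,
     "gloss": "a region or position on the surface of a molecule where something binds or takes place"},
    {"id": "binding_site", "hypernym": "site", "words": ["pocket", "groove", "cleft", "interface", "interfacial"], "count": 12,
     "gloss": "a site on the surface of a protein where a partner molecule makes physical contact"},
    {"id": "active_site", "hypernym": "site", "words": ["catalytic"], "count": 6,
     "gloss": "a site on an enzyme where a substrate binds and a reaction is accelerated"},
    {"id": "whole", "hypernym": "object", "words": ["whole"], "count": 10,
     "gloss": "an assemblage of parts regarded as a single object"},
    {"id": "unit", "hypernym": "whole", "words": ["unit"], "count": 8,
     "gloss": "a single undivided whole"},
    {"id": "molecule", "hypernym": "unit", "words": ["molecule"], "count": 14,
     "gloss": "the smallest unit of a substance retaining its chemical identity"},
    {"id": "macromolecule", "hypernym": "molecule", "words": ["macromolecule"], "count": 6,
     "gloss": "a very large biological molecule built from smaller subunits"},
    {"id": "protein", "hypernym": "macromolecule", "words": ["protein", "receptor", "enzyme", "antibody", "ligand"], "count": 25,
     "gloss": "a macromolecule composed of amino acid residues folded into a structure"},
    {"id": "small_molecule", "hypernym": "molecule", "words": [], "count": 6,
     "gloss": "a molecule of low molecular weight"},
    {"id": "compound", "hypernym": "small_molecule", "words": ["compound"], "count": 5,
     "gloss": "a small molecule formed from chemical elements"},
    {"id": "nucleotide", "hypernym": "compound", "words": ["nucleotide", "purine", "pyrimidine"], "count": 9,
     "gloss": "a compound consisting of a nitrogenous base a sugar and a phosphate group"},
    {"id": "phenomenon", "hypernym": "physical_entity", "words": ["phenomenon"], "count": 12,
     "gloss": "any state or occurrence open to observation"},
    {"id": "process", "hypernym": "phenomenon", "words": ["process"], "count": 10,
     "gloss": "a sustained phenomenon marked by gradual changes"},
    {"id": "natural_process", "hypernym": "process", "words": [], "count": 8,
     "gloss": "a process existing in or produced by nature"},
    {"id": "chemical_process", "hypernym": "natural_process", "words": ["reaction"], "count": 9,
     "gloss": "a natural process determined by changes in the composition of substances"},
    {"id": "modification", "hypernym": "chemical_process", "words": ["modification"], "count": 7,
     "gloss": "a chemical process that alters a group attached to a macromolecule"},
    {"id": "phosphorylation", "hypernym": "modification", "words": ["phosphorylation"], "count": 8,
     "gloss": "a modification attaching a phosphate group to a residue"},
    {"id": "glycosylation", "hypernym": "modification", "words": ["glycosylation"], "count": 5,
     "gloss": "a modification attaching a sugar chain to a residue"},
    {"id": "catalysis", "hypernym": "chemical_process", "words": ["catalysis"], "count": 6,
     "gloss": "acceleration of a reaction by an agent that is itself unchanged"},
    {"id": "biological_process", "hypernym": "natural_process", "words": [], "count": 7,
     "gloss": "a natural process carried out by living organisms"},
    {"id": "gene_process", "hypernym": "biological_process", "words": [], "count": 5,
     "gloss": "a biological process acting on genetic information"},
    {"id": "expression", "hypernym": "gene_process", "words": ["expression"], "count": 8,
     "gloss": "production of a gene product from genetic information"},
    {"id": "abstraction", "hypernym": "entity", "words": ["abstraction"], "count": 30,
     "gloss": "a general concept formed apart from concrete realities"},
    {"id": "quality", "hypernym": "abstraction", "words": ["quality"], "count": 15,
     "gloss": "an essential and distinguishing characteristic"},
    {"id": "attribute", "hypernym": "quality", "words": ["attribute"], "count": 10,
     "gloss": "a quality belonging to a particular thing"},
    {"id": "property", "hypernym": "attribute", "words": ["property"], "count": 9,
     "gloss": "a basic or essential attribute shared by members of a class"},
    {"id": "physical_property", "hypernym": "property", "words": [], "count": 8,
     "gloss": "a property measurable without altering identity"},
    {"id": "thermal_property", "hypernym": "physical_property", "words": [], "count": 5,
     "gloss": "a property relating to heat"},
    {"id": "temperature", "hypernym": "thermal_property", "words": ["temperature"], "count": 9,
     "gloss": "the degree of hotness of a body"},
    {"id": "structural_property", "hypernym": "physical_property", "words": [], "count": 6,
     "gloss": "a property arising from arrangement of parts"},
    {"id": "stability", "hypernym": "structural_property", "words": ["stability"], "count": 7,
     "gloss": "resistance to change or unfolding"},
    {"id": "polarity", "hypernym": "structural_property", "words": ["polarity", "polar"], "count": 6,
     "gloss": "unequal distribution of electric charge"},
    {"id": "act", "hypernym": "entity", "words": ["act", "action"], "count": 35,
     "gloss": "something done by an agent"},
    {"id": "contact_act", "hypernym": "act", "words": ["touch", "contact"], "count": 20,
     "gloss": "the act of making physical contact with the surface of another object"},
    {"id": "binding_act", "hypernym": "contact_act", "words": ["binding", "bind", "attachment", "association"], "count": 18,
     "gloss": "the act of making physical contact with a binding site on the surface of a molecule and holding to it"},
    {"id": "docking_act", "hypernym": "contact_act", "words": ["docking", "anchoring"], "count": 8,
     "gloss": "the act of fitting one molecule onto the binding site of a partner by physical contact"},
    {"id": "interaction_act", "hypernym": "act", "words": ["interaction", "recognition"], "count": 14,
     "gloss": "the act of mutual influence between two partners in contact"},
    {"id": "separation_act", "hypernym": "act", "words": ["separation"], "count": 6,
     "gloss": "the act of setting things apart"},
    {"id": "dissociation_act", "hypernym": "separation_act", "words": ["dissociation", "release"], "count": 7,
     "gloss": "the act of coming apart into separate components"}
  ]
}
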