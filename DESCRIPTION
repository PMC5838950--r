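Package: tmdock
Title: Text-Mined Binding-Site Residues as Protein Docking Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts protein-protein binding-site residue mentions from
    literature abstracts and turns them into confidence-ranked docking
    constraints. Residue mentions are recognized in sentence text, checked
    against the protein structures (name/number correspondence, solvent
    accessibility), and filtered by natural-language context analysis:
    keyword-dictionary spotting, semantic similarity to generic concept
    words, inverse parse-tree-distance scoring of residues against
    binding-site-relevant and -irrelevant keywords, and a kernel SVM over
    sentence and context features. Surviving residues are scored by
    abstract provenance (AND/OR query), converted into docking constraints,
    and used to rescore rigid-body docking poses; docking quality is
    assessed by ligand interface C-alpha RMSD. Includes seeded generators
    of labeled synthetic corpora, toy complexes and pose sets so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
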