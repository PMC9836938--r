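Package: depsicode
Title: Codon Reassignment and Mass Theory for Encoded Macrocyclic
    Peptides and Depsipeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational layer for genetic-code-reassignment experiments
    in codon-compressed (Syn61-derived) Escherichia coli: elemental-formula
    arithmetic with monoisotopic, average and nominal mass modes; a registry
    of canonical amino acids, non-canonical amino acids and alpha hydroxy
    acids; frame-aware codon compression and translation under codon
    reassignment schemes; neutral and ion mass prediction for linear and
    cyclic peptides and depsipeptides including ester-bond hydrolysis
    products; ring-opening a/b/y fragment-ion theory for cyclic molecules
    with tolerance-based peak annotation; automated identification of
    mutually orthogonal synthetase/monomer pairs from normalized
    fluorescence activity matrices; gel-fluorescence peptide quantification
    with internal-standard correction; and seeded synthetic-data generators
    for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
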