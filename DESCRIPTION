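Package: pseaacg
Title: General-Form Pseudo-Amino-Acid Composition Descriptors for Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates the thirteen standard modes of general-form pseudo-amino-acid
    composition (PseAAC) descriptors from FASTA protein sequences: amino-acid,
    di-peptide and tri-peptide composition, Type I and Type II PseAAC,
    normalized Moreau-Broto, Moran and Geary autocorrelation families,
    composition-transition-distribution (CTD) descriptors, quasi-sequence-order
    descriptors, binary gene-ontology and functional-domain annotation modes,
    and a PSSM-based sequential-evolution mode (PsePSSM). Any AAindex-style
    physicochemical property table can back the property-driven modes. A mode
    registry supports user-defined plugin modes, and a streaming batch engine
    writes CSV, TSV or svmlight feature matrices for large datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
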