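Package: fpbrowse
Title: Multi-Fingerprint Similarity Search for Small-Molecule Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Library preparation, fingerprinting and exact nearest-neighbour
    retrieval for SMILES compound collections. Molecules are standardized
    (counter-ion removal, rule-based pH 7.4 ionization) and annotated with
    formula and hydrogen-bonding counts; four fingerprint encodings are
    provided (a 1024-bit hashed substructure path fingerprint, a 1024-bit
    extended-connectivity fingerprint of bond diameter 4, 42 molecular
    quantum number counts and 34 SMILES character counts). A total-sum keyed
    hash index supports exact city-block-distance nearest-neighbour search
    with vendor and property filters, hit lists can be clustered with seeded
    K-means, and ligand-based virtual-screening decks can be scored by ROC
    AUC and enrichment factors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
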