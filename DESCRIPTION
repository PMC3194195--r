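Package: sap3d
Title: Structure-Aware Prediction of Disease-Related Amino Acid Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts whether a single amino acid polymorphism (SAP) is
    disease-related or neutral using a support vector machine with a radial
    basis function kernel. Input features combine the substitution itself,
    the three-dimensional structural environment of the mutated residue
    (residue composition of a 6 Angstrom shell around the C-alpha plus the
    relative solvent accessibility), sequence-profile statistics including a
    conservation index, protein-family scores, and a Gene Ontology log-odds
    term. Includes a sequence-only variant for comparison, homology-aware
    cross-validation with sequence-identity clustering, reverse-mutation
    class balancing, reliability-index filtering, and log-odds analysis of
    residue contacts lost and gained upon mutation. A synthetic-fixture
    generator produces structures, alignments, ontologies and labeled
    mutation sets with planted effect sizes for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    e1071,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
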