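Package: ppilr
Title: Protein-Protein Interaction Prediction by Binned Likelihood-Ratio Integration
Version: 0.1.0
Authors@R:
    person("PPI", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Naive-Bayes integration of heterogeneous protein-protein
    interaction (PPI) evidence. Per-channel scores (structural modeling,
    protein-peptide, partner redundancy, gene ontology, phylogenetic
    profile, orthology, cross-species expression correlation) are binned
    and converted to likelihood ratios against positive/negative reference
    interaction sets, then multiplied into a single combined likelihood
    ratio with a reliability cutoff. Includes the orthology interaction
    vectors with dimensional backoff, partner-redundancy features with a
    two-network fallback, the cross-species coexpression score, evaluation
    machinery (ROC curves, recovery fractions, compartment-crossed
    negative sets, protein-complex recovery by graph connectivity with a
    random-complex null, seeded complex-member prediction), ranked-list
    gene set enrichment for function annotation, variant-interface
    contingency statistics, a seeded synthetic-interactome generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
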