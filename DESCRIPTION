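Package: rxncomplete
Title: Completing Chemical Reaction Records by Heuristic Balancing and
    Masked Language Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for checking and completing chemical reaction records
    written as reaction SMILES. A heuristic balancer verifies atom and
    formal-charge conservation (hydrogen excluded), solves integer
    stoichiometry under a coefficient cap, and completes imbalanced
    reactions by adding curated help species or by promoting recorded
    reagent and solvent candidates to reactants. Reactions the balancer
    classifies as species-insufficient are passed to a masked language
    model over byte-pair-encoded reaction SMILES, which proposes missing
    molecules by mask-length enumeration; every proposal is re-verified by
    the balancer. A synthetic-reaction generator built on classic organic
    transformation templates provides fully balanced corpora with known
    corruptions for training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
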