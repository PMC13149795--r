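Package: morphclade
Title: Parsimony Analysis of Discrete Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for morphological cladistics of fossil taxa, built around
    anatomically preserved Palaeozoic seeds but applicable to any discrete
    unordered character matrix with unknown, inapplicable and polymorphic
    cells.  Provides a NEXUS reader/writer for morphological matrices,
    exact Fitch/Hartigan parsimony scoring with ambiguity, heuristic
    maximum-parsimony tree search (random addition plus tree
    bisection-reconnection) with an exhaustive oracle for small problems,
    strict and majority-rule consensus, bootstrap and Bremer branch support,
    ACCTRAN/DELTRAN/MPR-average character-state mapping, per-grade
    character-change-rate tables, Gower distance and principal coordinates
    disparity analysis, stratigraphic time-scaling with fossil-record gap
    detection, and a seeded Mk-style matrix simulator with full ground truth
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    cluster
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
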