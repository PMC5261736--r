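Package: kbscore
Title: Design and Evaluation of Knowledge-Based Scoring Potentials for
    Protein-Protein Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building, training and evaluating knowledge-based
    contact potentials that re-score rigid-body protein-protein docking
    decoys. Potential-specific feature vectors (distance-bin contact counts,
    soft Lennard-Jones r^-8/r^-6 sums, and per-atom-type buried surface
    areas) are precomputed once per decoy ensemble so that re-scoring is a
    single matrix-vector product. Parameters are trained either by a
    rank-weighted Monte-Carlo simulated annealing of a scoring-dependent
    target function or by ordinary/non-negative least-squares regression,
    with k-fold cross-validation and scaled parameter averaging. Decoy
    quality is assessed with CAPRI-style criteria (fraction of native
    contacts, interface and ligand RMSD, star classes), and trained
    potentials are evaluated by top-N success rates, near-native enrichment
    and discriminating per-parameter contributions against a random-scoring
    baseline. A synthetic-fixture generator produces toy rigid-body
    complexes, decoy ensembles with a controllable quality spectrum and
    planted linear energy models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
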