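Package: screenrank
Title: Multi-Criteria Profiling and Consensus Ranking of Compound Screening Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the rational selection of compound screening libraries.
    Candidate libraries (SDF or SMILES) are curated (salt stripping, removal of
    inorganics, mixtures, bad-valence structures and duplicates, one tautomer
    and protonation state per compound), profiled for ADME/T liabilities
    (Lipinski and Veber rule filters and a linear-plus-spline blood-brain
    barrier logBB model), screened for promiscuous binders against a SMARTS
    alert catalog, and scored for internal diversity and for similarity to
    reference actives and in-house collections using circular, structural-key
    and topological pharmacophore fingerprints with the Tanimoto coefficient.
    Per-criterion scores are combined by a two-level dense-rank consensus into
    a single library ranking. A genetic function approximation (GFA) engine
    with a lack-of-fit fitness rebuilds linear/spline QSAR models such as the
    shipped logBB equation, with kNN outlier filtering and Y-scrambling
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
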