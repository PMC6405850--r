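Package: loopscape
Title: Conformational Landscapes, Contacts and Sequence Statistics of
    Serpin Reactive-Centre Loops
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the conformational landscape of
    flexible protein loops, built around the serpin reactive-centre loop
    (RCL). Reads multi-model PDB ensembles, extracts loop backbone
    coordinates, performs principal component analysis and HDBSCAN
    density clustering with medoid representatives, computes RMSD/RMSF
    and backbone dihedral fingerprints with block averaging, measures
    salt-bridge occupancies between a loop and the protein body, scores
    local energetic frustration of residue contacts against
    composition-shuffled decoys, and implements alignment statistics
    (percent identity, entropy conservation, OMES/ELSC/SCA covariation
    with permutation significance). Boltzmann-sigmoid thermal melts and
    stoichiometry-of-inhibition assays are fitted from CSV tables. A
    seeded synthetic-data module generates multi-basin loop ensembles,
    two-state salt-bridge distance series, melt curves, inhibition
    assays and alignments with planted covariation, so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assays.R'
    'hdbscan.R'
    'structure_io.R'
    'metrics.R'
    'clustering.R'
    'coevolution.R'
    'frustration.R'
    'methods-accessors.R'
    'saltbridge.R'
    'pipeline.R'
    'synthetic.R'
    'utils.R'
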