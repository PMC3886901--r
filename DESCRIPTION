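Package: paleoprot
Title: Ancestral Protein Reconstruction and Ligand-Pocket Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood ancestral sequence reconstruction for protein
    alignments under empirical amino-acid models (JTT) with gamma-distributed
    rate variation and invariant sites, including empirical-Bayes marginal
    posteriors, AltAll robustness ancestors, and enumeration of amino-acid
    replacements on a focal branch with descendant-conservation filtering and
    reference-sequence numbering. Companion structural tools compute
    probe-occupied ligand-cavity volumes on a grid with flood-fill solvent
    exclusion and randomized orientations, least-squares superposition RMSD,
    pocket-lining residues, and pocket proximity of candidate substitutions.
    A simulation module generates alignments evolved on a tree with recorded
    ancestral states and toy structures with analytically known cavity
    volumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
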