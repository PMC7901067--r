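Package: molevolve
Title: Evolving GAN Training Data for Novel Small-Molecule Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generative adversarial search over small organic molecules
    represented as adjacency matrices (atom types on the diagonal, bond
    orders off-diagonal). Between training intervals, valid and novel
    generated molecules replace entries of the training population either
    at random or guided by a molecular score (drug-likeness,
    synthesizability or solubility), optionally after slice-crossover
    recombination with current training molecules, so the training data
    adapts like the population of a genetic algorithm. Includes the
    molecular scoring panel (QED-style drug-likeness, Ertl-style synthetic
    accessibility, logP-based solubility), Morgan-style fingerprints with
    Tanimoto distances, novelty tracking via canonical SMILES, QM9/ZINC
    style SMILES loaders and a download-free fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: OpenBabel (the 'obabel' command-line tool)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
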