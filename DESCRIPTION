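Package: loopcraft
Title: Full-Atom Protein Loop Modeling with Hierarchical Graph Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models missing or inaccurate protein loop regions at full heavy-atom
    resolution. A graph transformer encodes the covalent atom graph of the
    modeled pocket, geometric vector perceptrons encode a K-nearest-neighbor
    residue graph of the nonloop context, and the two levels are merged into a
    hierarchical representation. Loop coordinates are initialized from anchor
    geometry and moved by an attention-augmented E(n)-equivariant graph neural
    network with recycling; a mixture density network over loop-atom/residue
    distances provides the training likelihood and a per-conformation
    confidence score. Includes deterministic surface-pocket selection,
    synthetic helix-loop-helix fixture generation, a two-stage training
    protocol on a built-in reverse-mode autodiff engine, and RMSD-based
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
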