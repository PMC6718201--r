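Package: snapindex
Title: Indexing of Snapshot Crystal Diffraction Patterns by Gradient-Descent
    Lattice Finding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers one or more real-space crystal lattice bases from the
    noisy reciprocal-space Bragg-peak positions of a single still (snapshot)
    diffraction pattern, as recorded in serial crystallography experiments.
    Bragg peaks are mapped to reciprocal-space nodes via the Ewald
    construction; a periodic score transform built from per-node proximity
    functions is maximised by an extended gradient descent over a large set of
    starting points; candidate lattice bases are assembled from the maxima,
    reduced to shortest vectors, filtered by prediction counts and defect
    statistics, and refined by alternating least squares. Tolerates spurious
    peaks and superpositions of several lattices, with optional prior
    unit-cell knowledge. Includes a synthetic scene generator and an
    evaluation toolkit based on the Kabsch superposition angle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
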