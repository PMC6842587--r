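Package: peptoidsheet
Title: Peptoid Nanosheet Lattice Models and Synthetic Cryo-TEM Image
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds pseudo-atomic models of crystalline diblock
    polypeptoid nanosheets from backbone torsion recipes and lattice
    packing parameters, renders synthetic cryo-TEM-like projection
    micrographs (smooth lattice distortion, contrast transfer function,
    additive noise), and recovers structural observables with a
    2D electron crystallography pipeline: reciprocal-lattice indexing of
    power spectra, crystal unbending, unit-cell boxing, correlation-based
    classification and class averaging.  Reported observables include the
    a and c lattice spacings, parallel versus antiparallel V-motif
    packing fractions, the projected V dihedral angle, and heavy-atom
    (bromine) column positions.
License: MIT + file LICENSE
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
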