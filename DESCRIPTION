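Package: ringsym
Title: Rotational Symmetry Analysis of Ring-Shaped Particles and
    Oligomer Interface Characterization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to estimate the rotational symmetry order
    (stoichiometry) of ring-shaped macromolecular complexes from boxed
    negative-stain electron microscopy particle images, via polar
    resampling of an annulus, circular autocorrelation of the angular
    intensity profile, and Fourier analysis of the autocorrelation.
    Includes a synthetic ring-particle generator with ground truth for
    validation, MRC/MRCS stack input and output, stack-level analysis
    with per-order histograms, and a companion module for crystal
    structures of oligomers: C-alpha superposition, assembly grouping
    by contact graph, pseudo point-group (D2) detection, and
    protein-protein interface residue, salt-bridge and hydrophobicity
    characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    withr,
    EBImage,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: ElectronMicroscopy, ImageAnalysis, StructuralPrediction, Software
RoxygenNote: 7.3.3
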