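Package: cryosse
Title: Secondary Structure Segmentation of Medium-Resolution Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects alpha-helix and beta-sheet regions in medium-resolution
    (5-10 Angstrom) cryo-EM component density maps with an end-to-end 3D U-Net
    voxel classifier. Provides MRC2014 volume input/output with resampling to
    1 Angstrom voxels, chain-envelope extraction, STRIDE-based ground-truth
    voxel labeling, a 3D U-Net (R with C++ convolution cores) trained with
    weighted cross-entropy plus Dice
    loss trained by a three-phase curriculum with gradient-episodic-memory
    projection, voxel- and residue-level F1 evaluation with majority voting,
    dataset curation (sequence-identity de-duplication, cylindrical-fit
    quality binning, TM-score screening), and a seeded synthetic density-map
    generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
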