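Package: monoshape
Title: Monocular 3D Shape Reconstruction from Images of Mirror-Symmetric Objects
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational model of monocular 3D shape reconstruction from
    single orthographic or perspective images of mirror-symmetric objects.
    Implements RANSAC detection of primary and secondary mirror-symmetry
    planes of a mesh, the one-parameter family of symmetric 3D
    interpretations of a corrected orthographic image indexed by
    symmetry-plane slant, shape selection by maximum compactness (V^2/S^3),
    modified compactness (V/S^3) and a two-plane depth-consistency loss,
    vanishing-point slant estimation from perspective images, and a
    lambda-weighted linear cue-combination model fit by least squares.
    Includes a seeded generator of random and rectangular mirror-symmetric
    polyhedral stimuli, projection and orientation-noise models, mesh file
    I/O (OBJ, OFF, ASCII PLY), and an end-to-end evaluation pipeline based
    on a tan-ratio shape-dissimilarity metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
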