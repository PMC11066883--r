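Package: diffusemap
Title: Reciprocal-Space Mapping, Scaling and Merging of Macromolecular
    Diffuse Scattering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing three-dimensional maps of diffuse
    X-ray scattering from rotation-series diffraction data.  Photon counts
    are accumulated on an oversampled reciprocal-space voxel grid with
    Bragg-peak ellipsoid masking, corrected for background and geometric
    factors, scaled with a regularized four-parameter model refined by
    alternating least squares, and merged by Laue symmetry with
    inverse-variance weights.  Includes split-half correlation statistics
    (CC1/2, CC_Friedel, CC_Rep) by resolution shell, symmetry expansion
    and isotropic subtraction for visualization, and a synthetic-experiment
    simulator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    parallel,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
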