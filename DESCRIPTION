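Package: octa3d
Title: Rotational 3D OCT Angiography Analysis of Type 3 Macular
    Neovascularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Volumetric analysis pipeline for swept-source OCT angiography
    (OCTA) cubes of eyes with type 3 macular neovascularization. Provides
    raw/TIFF volume input-output with axial-first reorientation, a
    volumetric projection (decorrelation-tail) artifact removal algorithm
    operating on thin overlapping depth subvolumes, retinal-layer slab en
    face projection with 2D lesion counting, 3D lesion detection and
    morphometry (saccular versus filiform shape, inclination relative to
    the Bruch's membrane plane, sub-RPE contact, trunk merging),
    rotational maximum-intensity-projection rendering of merged
    structure/flow volumes, and cohort summary statistics. A synthetic
    macular-cube phantom with planted lesions of known geometry supplies
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
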