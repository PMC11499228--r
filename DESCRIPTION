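Package: punctnav
Title: CT and Structured-Light Guided Orthopedic Puncture Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software core of a computed-tomography plus structured-light-imaging
    (SLI) guided orthopedic puncture navigation workflow. Builds preoperative
    navigation maps from CT volumes by Hounsfield-unit threshold segmentation and
    isosurface extraction; registers intraoperative surface point clouds to the CT
    surface model by coarse landmark alignment followed by trimmed iterative
    closest point refinement; tracks a cylindrical puncture guiding tube by RANSAC
    cylinder fitting and scores it against a planned path; and quantifies
    pre/intra/postoperative surface and skeletal drift with RMS distance fields,
    per-vertex heat maps and cohort statistics. Includes a synthetic limb phantom
    generator (CT voxelization, structured-light scan simulation, tube clouds,
    known-drift injection) so every stage has a generate-and-recover test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
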