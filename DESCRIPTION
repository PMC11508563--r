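Package: panflute
Title: 3D Planning Toolkit for Curved Intra-Articular Corrective
    Osteotomies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tibial plateau malunions against the mirrored
    contralateral bone (six-parameter quantitative 3D CT deformity
    analysis), plans curved intra-articular osteotomies as ordered sets
    of depth-controlled drill trajectories along the old fracture line,
    generates the three 3D-printable patient-specific guide solids
    (Panflute cutting guide with per-hole depth-stop tubes, intermediate
    pre-drill guide, and plate-referencing reposition guide), and
    assesses achieved versus planned fragment position.  A parametric
    proximal-tibia phantom generator with exactly known ground truth
    supports end-to-end validation of every pipeline stage, from CT
    segmentation to deformity decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
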