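Package: resectplanr
Title: Automated Convex-Hull Resection Planning for Bone Tumor Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates and optimizes elaborate (non-planar) resection
    geometries for en-bloc bone tumor surgery. Segmented bone and tumor
    surface meshes (STL/PLY, millimeters) are embedded in a uniform voxel
    grid by ray casting; three convex-hull resection geometries (conical,
    flat-based, contoured) are constructed from a small vector of rotations
    and translations; and the fraction of healthy bone collaterally
    resected ("bone waste") is minimized by bounded particle swarm
    optimization with restarts. Includes a parametric synthetic phantom
    generator (long-bone-like shaft with condylar bulge and spherical,
    ellipsoidal or lobed tumors) so the full pipeline can be exercised and
    validated without patient data, a planar-resection baseline for
    comparison, and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
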