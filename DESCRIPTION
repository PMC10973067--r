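Package: cowflow
Title: Synthetic Circle-of-Willis Phantoms, Vessel Segmentation and
    Reduced-Order Pulsatile Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the complexity of a cerebrovascular
    model (the number of outflow branches retained) affects simulated
    intracranial hemodynamics. Provides a synthetic angiography phantom
    generator (Circle-of-Willis-like vessel networks rasterized into
    time-of-flight-like 3D volumes with ground truth), a vessel
    segmentation chain (multiscale Hessian vesselness, seeded region
    growing, isosurface extraction, Laplacian smoothing, end cutting and
    extrusion), centerline network extraction with outlet trimming and
    parametric aneurysm attachment, a reduced-order pulsatile blood-flow
    solver on the vessel graph with Murray's-law outlet splitting and
    analytic Womersley velocity-profile reconstruction, and hemodynamic
    evaluation metrics (TAWSS, OSI, aneurysm neck inflow rate, normalized
    velocity profiles, centerline velocity curves) with paired
    complex-versus-trimmed model comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
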