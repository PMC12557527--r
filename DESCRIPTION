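Package: fibertfm
Title: Reference-Free 3D Traction Force Microscopy on Deformable Fiber Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers three-dimensional cell traction forces from the
    deflections of suspended microfabricated fibers. Models each fiber as a
    clamped Euler-Bernoulli beam under built-in axial tension (bending plus
    geometric stiffness finite elements), extracts per-fiber deflection
    fields from multi-channel 3D fluorescence stacks without a stress-free
    reference image, and solves a contact-constrained, elastic-net
    regularized convex inverse problem for the nodal force vector. Includes
    closed-form stiffness regimes and tension calibration from AFM apparent
    stiffness, a synthetic phantom generator (scaffold layouts, ground-truth
    force patterns, rendered noisy image stacks) for end-to-end validation,
    and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
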