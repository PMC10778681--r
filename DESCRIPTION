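Package: helixframe
Title: Discrete Frenet-Frame Geometry and Critical-State Free Energy of DNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a discrete Frenet frame along the helical axis of a DNA
    duplex, extracts zyz Euler angles and their period-corrected differences
    (including the per-step gauge potential, the rotation angle between
    consecutive base pairs), converts them into geodesic curvature, normal
    curvature and geodesic torsion, evaluates a Landau-type critical-state
    free-energy density per site, and classifies the helix chirality
    (right-handed B-form versus left-handed Z-form). Reads duplexes from PDB
    files, reducing each deoxynucleotide to the mean of its C3', C4', O3' and
    C1' atoms, and ships a generator of ideal synthetic duplexes plus the
    closed-form circular-helix curvature and torsion used as analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
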