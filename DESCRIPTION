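Package: capgen
Title: Generation of 3D-Printable Flexible Head Caps for fNIRS and EEG
Version: 0.1.0
Authors@R:
    person("capgen", "developers", email = "capgen@example.org", role = c("aut", "cre"))
Description: Tools to turn a scalp surface mesh, a probe design (optodes,
    springs, anchors, grommet types) and a target head circumference into
    four 3D-printable flat cap panels. The pipeline constructs EEG 10-5
    landmarks on the scalp by iterative arc subdivision, registers the
    probe onto the head by spring relaxation with landmark anchors, cuts
    the scalp into panel surfaces, flattens each panel with an iterative
    gravity plus spring-relaxation scheme that preserves local distances,
    fills the flattened outlines with a hexagonal lattice, generates
    welding tabs along panel seams, and extrudes watertight solids with
    grommets, ear slits and strap holders, written as STL.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
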