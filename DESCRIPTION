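Package: mctmorph
Title: Automated Morphometry of Bone Scaffolds from Micro-CT Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic, user-independent quantification of porous
    bone-substitute scaffolds imaged by X-ray micro-computed tomography.
    Reads reconstructions stored as TIFF slice stacks, segments the dense
    scaffold phase with a fuzzy-c-means-derived global threshold seeded at
    the construct's centre of mass, extracts pores as largest inscribed
    spheres from the Euclidean distance map of the void phase inside the
    construct's convex hull, and reports a standardized morphometric
    parameter set (total volume, scaffold volume, surface, porosity, pore
    number/size/volume, mineral-density statistics). Cohort-level routines
    compare two acquisition time points per construct with normality-routed
    paired tests and merged pore-size and attenuation histograms. Includes
    a synthetic phantom generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
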