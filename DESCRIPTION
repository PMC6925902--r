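Package: isomask
Title: Keyed Affine Geomasking of Confidential Point Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sharing confidential health point data (for example geocoded
    patient addresses) with external spatial analysts without revealing true
    locations. A keyed affine geomask displaces every point by one random
    translation followed by one quarter-turn rotation, so pairwise distances and
    therefore spatial structure are preserved; the secret (random number, angle,
    offset intervals, masked extent) is held in a local key store and supports
    exact re-transformation of the points, and of raster surfaces (kernel density,
    inverse-distance interpolation) computed by a collaborator in the masked
    geography, back to the original geography. Includes from-scratch point-pattern
    statistics (average nearest neighbour, Ripley's K) used to verify that masking
    leaves analytical results unchanged, a clustered and completely-spatially-random
    synthetic point generator, ESRI shapefile and ASCII-grid raster input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    foreign,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
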