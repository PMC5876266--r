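Package: mpcpr
Title: Multipath Curved Planar Reformation of Peripheral CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for peripheral CT angiography in
    peripheral arterial disease. Generates synthetic contrast-enhanced
    arterial-tree phantoms with ground-truth centerlines and lesions, tracks
    vessel centerlines semiautomatically by minimum-cost paths with
    lumen-centroid recentering, renders attenuation-preserving curved planar
    reformations (CPR), multipath CPRs and bone-suppressed maximum intensity
    projections as rotation series, quantifies lumen caliber to grade
    stenoses per anatomical segment against the 70 percent significance
    rule, and computes clustered diagnostic-performance and inter-reader
    agreement statistics against a reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    sandwich,
    optparse,
    yaml
Config/testthat/edition: 3
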