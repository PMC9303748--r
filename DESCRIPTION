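Package: myoquant
Title: Automated Quantification of Myogenic Cell Cultures from Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments nuclei in multi-channel 8-bit immunofluorescence images
    (IsoData auto-thresholding, distance-transform watershed, size and border
    filtering), calls per-nucleus marker positivity by segment colocalization,
    recognizes multinucleated MyHC-positive myotubes, and computes the
    proliferation, differentiation and fusion indices used to characterize
    satellite-cell cultures. Includes a synthetic-image generator with full
    ground truth emulating coated-well culture studies (coatings x days x
    wells x fields), and a statistics layer fitting linear models with
    data-driven coating-by-time interaction selection plus agreement
    statistics for validating automated against manual counts.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    digest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
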