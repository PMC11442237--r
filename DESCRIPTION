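Package: hatcat
Title: Highly Adaptive Testing with Shadow-Test Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Engine and simulator for the highly adaptive testing (HAT)
    design: computerized adaptive testing with items nested in
    stimulus-sharing units, item response theory models (2PL and the
    generalized partial credit model), shadow-test automated assembly by
    mixed-integer programming under blueprint constraints, progressive
    item-exposure control, response-probability-shifted item selection,
    item-position balancing via subpool ordering, spiraled link units,
    and a full simulation harness (synthetic pools, correlated simulees,
    accuracy/exposure/violation metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
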