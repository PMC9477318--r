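Package: whiskmap
Title: Whisker Mechanics and Three-Dimensional Contact-Point Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quasistatic deflections of a tapered, intrinsically
    curved rat whisker (vibrissa) over its reachable space, computes the six
    reaction forces and moments at the whisker base, and builds invertible
    lookup-table mappings from triplets of mechanical signals to the
    three-dimensional whisker-object contact point. Includes uniqueness
    testing of all twenty signal triplets with neural-network function
    approximation and geometric overlap scans, numerical Jacobian sensitivity
    analysis of the contact-point mapping, and a synthetic whisking-against-a-peg
    generator used to demonstrate contour reconstruction of a vertical peg in
    the laboratory frame.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
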