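Package: opinionfield
Title: Co-Evolving Opinion Dynamics Under an External Media Field
Version: 0.1.0
Authors@R:
    person("opinionfield", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator of continuous opinion formation on a
    co-evolving social network subject to a homogeneous external field that
    mimics mass-media influence. Opinions evolve on a fast transaction time
    scale with conviction freezing at the extremes, while the network rewires
    on a slow generation time scale by disagreement-driven link cutting and
    link creation through triadic or focal closure. The package also provides
    the mean-field reduction of the model (cubic fixed-point equation,
    stability eigenvalue, critical field) and a survey-calibration procedure
    that assigns a field strength to science-perception statements from their
    agreement fractions, with the 15-statement Eurobarometer/Mexican survey
    table packaged as plain-text data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
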