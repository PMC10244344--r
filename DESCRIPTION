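Package: popmln
Title: Measurement Stack for Population-Scale Multilayer Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing node-aligned multilayer social networks of the
    kind derived from administrative registers, where people are connected
    through close family, extended family, household, next-door neighbour,
    school and work layers. Implements the measurement stack for such
    networks: layer, total and unique-neighbour degree systems with
    missing-family inverse-probability weighting and disclosure-aware
    histograms; per-edge embeddedness and tie range via an alternating
    breadth-first search; local clustering and an excess-closure measure that
    separates within-layer (expected) triadic closure from closure created by
    the interaction of layers; exact giant-component diameters and sampled
    average shortest path lengths; and exact or pivot-approximated closeness
    centrality. A synthetic register-style population generator reproduces the
    six layer-construction mechanisms (family trees with partner links,
    household cliques, 50-metre next-door assignment capped at 10 households,
    school-group cliques, and small-workplace cliques with geographic
    100-nearest sampling in large workplaces) so that every measure can be
    exercised without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
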