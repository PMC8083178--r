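Package: hicsig
Title: Significance Calling of Long-Range Contacts in Hi-C Maps
Version: 0.1.0
Authors@R: person("Regulome", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies statistically significant long-range cis contacts in
    Hi-C maps at two scales. In regions mode, interaction profiles around
    short (1-3 bin) anchors are scored against a distance-matched Weibull
    background fitted per diagonal, with Benjamini-Hochberg FDR control and
    an all-replicates intersection rule. In domains mode, the bin map is
    aggregated into a domain-pair contact matrix and pairs are scored under
    hypergeometric, Poisson or negative-binomial nulls. Includes A/B-style
    compartment classification from the first principal component of the
    observed/expected correlation map, call-set comparison with bin
    tolerance, ChIP-seq peak enrichment tests, a synthetic map generator
    with planted ground truth, and a command-line interface with profile
    and triangular map plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
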