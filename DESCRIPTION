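Package: canet
Title: Cross-Species Discovery of Conserved Active Subnetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers conserved and species-specific active subnetworks by
    overlaying differential-expression activity scores on weighted functional
    linkage networks of two species linked by ortholog clusters. Subnetworks
    are grown greedily from differentially active seed genes, adding nearby
    genes reached through high-confidence (max-product) paths while a minimum
    average activity score and a minimum average weighted clustering
    coefficient are maintained in both species. Includes a single-species
    variant, permutation-based significance assessment by shuffling activity
    labels over network genes, hypergeometric enrichment of subnetwork members
    with Bonferroni correction, and a synthetic two-species benchmark
    generator with planted modules and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
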