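Package: coralnet
Title: Resistance and Robustness Analysis of Coral-Symbiont Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building bipartite networks of coral hosts and their
    Symbiodiniaceae symbionts from association records, assigning thermal
    tolerances to hosts (from bleaching-response indices) and symbionts (from
    thermal-tolerance rank scores), simulating coral bleaching as a
    temperature-ramped link-removal process, and quantifying network
    resistance to temperature stress and ecological robustness (R50) under
    link- and node-removal attack models. Includes degree-preserving and
    non-degree-preserving bipartite null networks, tolerance-randomisation
    nulls, permutation tests with significance-letter groupings for comparing
    simulation ensembles, and a synthetic-data generator that emulates the
    sparse, heavy-tailed structure of the global coral-symbiont network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
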