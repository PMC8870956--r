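Package: supportnet
Title: Social Support Profiling of Online Health Communities via Word
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sentence-window word co-occurrence networks from online
    health community posts, characterises them with small-world and
    scale-free diagnostics (average shortest-path length, clustering
    coefficient, Erdos-Renyi baselines, power-law degree exponent), detects
    word modules by resolution-parameterised modularity optimisation
    (Louvain), and quantifies the share of informational, emotional and
    companionship support per disease group through within-module edge
    proportions, with chi-squared comparison across groups. Includes a
    planted-structure synthetic corpus generator so the whole pipeline is
    testable without access to any proprietary forum crawl.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
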