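Package: seedbench
Title: Benchmarking Seeding Strategies for Spreading Processes on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks seed-node selection strategies for cascade
    susceptible-infected (SI) spreading processes on undirected social
    networks. Generates scale-free networks with tunable clustering in
    density/clustering categories, selects seed sets by five centralized
    (degree, betweenness, closeness, PageRank, k-core), four decentralized
    (Vote-Rank, ambassadors, community hubs, random hubs) and one random
    strategy, measures spreading efficiency (time to infect the largest
    connected component), ranks strategies by pairwise outperformance, and
    quantifies seed-set overlap with a degeneracy (Jaccard) coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
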