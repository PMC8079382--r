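Package: tagnet
Title: Hashtag Co-Occurrence Networks for Cultural Ecosystem Services Discourse
Version: 0.1.0
Authors@R: person("tagnet", "maintainers", email = "tagnet@example.org", role = c("aut", "cre"))
Description: Builds and analyses hashtag co-occurrence networks from social-media
    post corpora to characterise the cultural-ecosystem-services discourse around
    natural areas. Provides a synthetic corpus generator with planted topic
    structure, bots and advertising posts; corpus cleaning (near-duplicate bot
    detection, blocklists, synonym and misspelling merging); per-area weighted
    co-occurrence graphs with top-frequency hashtag selection; from-scratch
    centrality measures (eigenvector via power iteration, Brandes node and edge
    betweenness, degree and strength); fast-greedy (Clauset-Newman-Moore)
    modularity communities with lexicon-assisted labelling; and a cross-area
    merged network with bridge-hashtag identification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stringi,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
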