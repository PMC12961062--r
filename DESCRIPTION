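Package: branchmap
Title: Mapping and Assessing Decision-Making in Branched Clinical Case Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for choose-your-own-adventure style branched clinical
    case studies (diagnostic branched trees). Models a case as a directed
    acyclic graph with an expert route and per-option classifications
    (expert, tolerable, incorrect), replays branching-form response logs
    into user paths, classifies cumulative decision-making behavior at each
    expert-route checkpoint, tabulates cohort behavior, and renders
    deterministic traffic-weighted Graphviz DOT maps. Includes a stochastic
    cohort simulator so every pipeline stage is testable without human
    participant data, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
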