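Package: claimsrank
Title: Bipartite Centrality and Survival Models for Prescription Claims Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds rolling-window bipartite patient-provider networks from
    longitudinal prescription claims, estimates the family of bipartite
    centrality indices (HITS, CoHITS, BGRM, BiRank) together with PageRank on
    the one-mode patient projection, and relates the resulting scores to
    subsequent overdose events through Cox proportional-hazards models
    compared by AIC. Includes a synthetic claims generator that emulates the
    statistical structure of commercial claims data (latent drug-seeker
    subpopulation clustering on lenient high-volume prescribers, right-skewed
    morphine-milligram-equivalent edge weights, rare events, censoring by
    disenrollment), so the full analysis is testable without access to
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    survival,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
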