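Package: pathfp
Title: Drug Mechanism-of-Action Inference from Drug-Target-Pathway
    Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("pathfp", "maintainers", email = "pathfp@example.org",
           role = c("aut", "cre"))
Description: Integrates multi-source drug-target evidence into combined
    confidence scores by noisy-OR aggregation, assembles a
    drug-target-pathway heterogeneous information network from the
    thresholded interactions and GMT gene-set collections, and compares
    drugs two ways: by target-profile (Jaccard) similarity and by
    PathSim similarity over the drug-target-pathway-target-drug
    metapath (pathway fingerprints). Includes agglomerative hierarchical
    clustering with deterministic tie-breaking, extraction of shared
    metapath subgraphs to predict pathway associations of a query drug,
    scoring of pathway regulation direction from differential-expression
    tables (up-regulated gene ratios), a synthetic-data generator with
    planted mechanism-of-action structure for end-to-end validation, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
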