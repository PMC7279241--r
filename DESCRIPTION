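Package: targetfishr
Title: Ligand-Based Target Prediction with Similarity and Random-Forest
    Rankers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A ligand-based target-fishing pipeline: curation of raw
    bioactivity records (ChEMBL-style tables) into a labeled compound-target
    knowledge base, two target rankers (nearest-neighbor maximum Tanimoto
    similarity with iterative tie-breaking, and binary-relevance random
    forests with presumed-inactive augmentation), and a top-k evaluation
    framework that deconvolutes success and recovery rates by the similarity
    of each query to the knowledge base, under external-split, time-split and
    close-to-real-world scenarios. Includes a synthetic bioactivity generator
    so the full pipeline runs and is testable without any external database.
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
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
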