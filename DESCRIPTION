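Package: isofun
Title: Multispecies Protein Function Prediction from Homology-Informed
    Network Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates protein-protein interaction networks from several
    species with BLAST sequence homology by computing IsoRank diffusion
    similarity scores between and within proteomes. The resulting block
    similarity matrix provides a shared feature space over all species'
    proteins, on which a maxout neural network is trained to predict Gene
    Ontology terms. Includes leave-one-species-out network imputation via
    one-mode projection for organisms lacking interaction data, CAFA-style
    evaluation measures (macro/micro AUPR, top-3 F1, subset accuracy,
    F-max), a BLAST annotation-transfer baseline, ablation variants, and a
    synthetic multispecies data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
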