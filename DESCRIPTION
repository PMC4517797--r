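Package: ebclust
Title: Ensemble Biclustering for Classifying Entity-Pair Relationships in Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements Ensemble Biclustering for Classification (EBC), a
    distributional-semantics method for mining entity-pair relationships
    (for example drug-gene pairs) from dependency-parsed text corpora.
    Provides extraction of drug-to-gene dependency paths from pre-parsed
    sentence graphs, construction and filtering of binary pair-by-path
    co-occurrence matrices, information-theoretic co-clustering (ITCC),
    ensembles of co-clustering runs summarised as co-clustering count
    matrices, rank-sum scoring of candidate pairs against small seed sets
    (with average-cosine, rank-sum-cosine and latent-semantic-analysis
    baselines), AUC-based benchmarking of seeded rankings, and mapping of
    the global relationship landscape via Spearman-correlation distances
    and minimax-linkage hierarchical clustering with prototypes. A
    synthetic-data module generates binary matrices with planted bicluster
    structure, including a synonymy scenario in which one relationship
    class is expressed through two disjoint sets of surface forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    graphics,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
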