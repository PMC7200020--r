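Package: SpongeModules
Title: Discovery of lncRNA-Related miRNA Sponge Modules from Matched
    Expression Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies groups of long non-coding RNAs (lncRNAs) that act
    collectively as microRNA (miRNA) sponges for a group of messenger RNAs
    (mRNAs), from matched miRNA, lncRNA and mRNA expression profiles plus
    putative miRNA-target interactions. Stage one detects lncRNA-mRNA
    co-expression modules with a weighted correlation network (soft
    thresholding chosen by scale-free fit, topological overlap,
    average-linkage clustering). Stage two retains modules whose lncRNA and
    mRNA groups share miRNAs significantly (hypergeometric test), are
    strongly canonically correlated, and lose a substantial share of that
    correlation when conditioning on the shared miRNAs (sensitivity
    canonical correlation). Module-level statistical significance is
    assessed with a Monte-Carlo null model and Benjamini-Hochberg
    adjustment. Downstream analytics cover disease-gene enrichment,
    single-sample enrichment scoring, subtype-specific module calling,
    survival biomarker evaluation, and module-based interaction prediction.
    A pairwise sensitivity-correlation network clustered with the Markov
    cluster algorithm is included as a comparison baseline, together with a
    synthetic-data generator that plants miRNA-mediated and decoy modules
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    survival,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
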