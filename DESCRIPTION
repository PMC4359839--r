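Package: lncFunNet
Title: lncRNA Function Prediction from Expression-Derived Regulatory Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology functions for long noncoding RNAs (lncRNAs)
    from RNA-seq derived expression profiles. Assembled genes are classified
    against reference annotation by exonic overlap, expression profiles are
    filtered by sample presence and discretized to two levels with Hartemink's
    mutual-information-preserving collapse, a Bayesian network over lncRNAs and
    protein-coding genes is learned by BIC-scored greedy hill climbing with
    random restarts, the lncRNA-incident regulatory network is extracted and
    characterized (degree, cis/trans, differential-expression edge categories,
    nearest neighboring genes), and each lncRNA is annotated by hypergeometric
    GO enrichment of protein-interaction modules mined from its linked genes
    via shortest-path distances, average-linkage clustering and a minimum-size
    tree cut. A synthetic-data generator produces all pipeline inputs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
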