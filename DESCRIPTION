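Package: topicomics
Title: Multi-Omic Integration of Gut Microbiome Data by Topic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent Dirichlet Allocation (LDA) on microbiome count tables with
    samples as documents and omic features (ASVs, KEGG orthologs, metabolites)
    as words, fitted by a collapsed Gibbs sampler. Includes median-of-ratios
    normalization with data-driven selection by the sibling distance ratio,
    posterior-predictive selection of the number of topics, cross-omic topic
    clustering validated against a multinomial null ensemble, dual-criterion
    topic interpretation, topic-driven sample clustering, shadow-feature
    random-forest differential-abundance screening with Wilcoxon/BH testing,
    Mantel comparison of beta-derived feature distance matrices across
    cohorts, and a synthetic multi-omic cohort generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
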