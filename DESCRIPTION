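Package: ciliaprior
Title: Ciliary Candidate Gene Prioritization from High-Content Screens
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested reimplementation of a candidate-gene prioritization
    workflow for ciliopathies such as Joubert syndrome. Curates
    positive/negative training labels against an evidence knowledge base,
    fuses siRNA screen replicates, centriole-screen reagent scores and
    tissue expression signatures into a per-gene feature matrix, scores
    every gene with a class-balanced bagged forest (out-of-bag scores,
    score-based FDR, high-confidence selection), validates rankings with
    ROC/precision-recall, one-tailed Wilcoxon, Jonckheere-Terpstra trend
    and hypergeometric enrichment statistics, intersects candidate genes
    with family exome variant tables through a filter cascade with
    compound-heterozygote handling, and computes replication-cohort allele
    statistics. A seeded synthetic-data module makes every stage testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
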