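Package: dynamed
Title: Dynamic Network and Bayesian Network Analysis of Inflammatory Mediator Time Series
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the longitudinal analysis of multiplexed inflammatory
    mediator panels (cytokines, chemokines, DAMPs) measured over time in
    clinical subgroups or experimental arms. Implements interval-wise signed
    Pearson correlation networks (dynamic network analysis, DyNA) with
    network complexity and per-mediator connectivity summaries; first-order
    dynamic Bayesian network inference scored with the Bayesian Gaussian
    equivalent (BGe) marginal likelihood, with node-specific changepoints
    sampled by Markov chain Monte Carlo, posterior edge probabilities,
    consensus graphs and self-feedback (central node) detection; outcome
    biomarker statistics (Mann-Whitney rank-sum, Spearman correlation,
    ROC/AUC with Youden-optimal cutoff, volcano classification); and a
    synthetic-data generator that emulates serum and hepatocyte-supernatant
    mediator panels with known planted structure so that every inference
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), pROC, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
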