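Package: mhmmclust
Title: Clustering Healthcare Utilization Trajectories with Mixtures of Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters variable-length monthly healthcare service utilization
    count series with a mixture of hidden Markov models (MHMM). Provides
    log-space forward-backward and Viterbi recursions (compiled), EM fitting
    of the mixture with restarts and size-ordered cluster labels, BIC/AIC
    model selection over a (clusters, states) grid, cluster summaries
    (stacked count/state tables, state labels, state diagrams), baseline
    comparisons against k-medoids (PAM, CLARA) and fuzzy c-means with
    silhouette and Dunn validity indexes and classical MDS projections, and
    multinomial logistic regression of cluster membership on claimant
    covariates. Includes a synthetic generator emulating transport-accident
    compensation claims data so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    e1071,
    nnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
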