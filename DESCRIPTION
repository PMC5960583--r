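Package: trammelcatch
Title: Catch Comparison and Discard Survival Analysis for Trammel-Net
    Fisheries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing catch, revenue and discards between
    trammel-net gear designs at the netting-wall level.  Implements a
    Bayesian hierarchical hurdle-exponential model fitted by
    Metropolis-within-Gibbs sampling with conjugate updates for occurrence
    probabilities, Gelman-Rubin convergence diagnostics,
    credibility-interval relevance decisions, immediate discard survival
    with beta-binomial credible intervals, Kaplan-Meier short-term
    survival, Hellinger-based ordination (principal components and
    redundancy analysis with permutation tests), deterministic
    catch-processing rules (length-weight conversion, length-class
    binning, subsample scaling, first-sale revenue), and a synthetic-data
    generator reproducing the hierarchical structure of observer-sampled
    trammel-net catches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
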