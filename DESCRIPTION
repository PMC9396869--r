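Package: bnomics
Title: Bayesian Network Inference of Regulatory Networks from Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene regulatory networks from matched gene expression,
    copy-number and DNA-methylation matrices by Markov chain Monte Carlo over
    directed acyclic graph structures. Structures are scored with the BGe
    marginal likelihood for Gaussian networks combined with an energy-based
    biological-knowledge prior; entries of the prior matrix that are unknown
    are replaced by empirical knowledge estimated from the chain's own
    proposal and acceptance statistics during an adaptive phase. Sampled DAGs
    are summarised as completed partially directed acyclic graphs (CPDAGs)
    and edge confidence is reported as the empirical edge frequency over two
    independent chains. Includes a linear-Gaussian multi-omics simulator with
    known ground truth and evaluation metrics (ROC/AUC with 83 percent
    confidence intervals, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
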