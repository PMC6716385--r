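Package: critmix
Title: Bayesian Mixture Modeling of Criterial and Degree Vagueness in
    Repeated Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates two sources of intraindividual variability in
    repeated category membership decisions: criterial vagueness (latent
    groups of respondents who order the items differently) and degree
    vagueness (respondent-specific thresholds on a shared ordering). A
    finite mixture of logistic item-response models is fitted by
    Metropolis-within-Gibbs MCMC; posterior draws are relabeled, checked
    for convergence, and summarized as posterior-mode group assignments
    per session, so that within-person criterion changes between two
    categorization sessions can be counted. Includes descriptive
    response-inconsistency statistics and a synthetic-data generator that
    emulates a two-session study design with controlled criterion
    switching, threshold drift, and unknown-response contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
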