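Package: cpmem
Title: Single-Case Abnormality Scores and Phenotypic Subtyping for
    Case-Control Recognition-Memory Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing case-control studies of long-term
    recognition memory, motivated by congenital prosopagnosia research.
    Simulates trial-level recognition cohorts under a binomial logistic
    mixed model; scores trial tables with signal-detection measures
    (error rate, miss/false-alarm split, d-prime with extreme-rate
    correction); fits binomial generalized linear mixed models by Laplace
    approximation with likelihood-ratio comparisons of nested models and
    Bayesian posterior summaries (highest posterior density intervals) by
    Metropolis-within-Gibbs sampling; computes leave-one-out single-case
    abnormality z-scores with modified t-test deficit calls; and clusters
    participant deficit profiles into phenotypic subtypes by complete
    linkage. A pipeline driver reproduces the whole analysis from a single
    seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    lme4,
    mclust,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
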