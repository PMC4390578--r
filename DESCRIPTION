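Package: orthofuse
Title: Ensemble Integration of Ortholog Predictions by Graph-Based
    Cluster Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates ortholog proposals from multiple, methodologically
    distinct ortholog-detection methods. Candidate sequences for a reference
    gene are arranged as nodes of a similarity-weighted graph, filtered with
    species-specific percent-identity cutoffs, and at most one ortholog per
    species is selected by cyclic coordinate descent with random restarts.
    Also provides the accompanying quality-assessment metrics (reference-
    denominated percent identity, head-to-head method comparison, normalized
    Robinson-Foulds tree concordance with a CDF-area summary, functional
    concordance, positively-selected-site overlap), post-filters for
    site-level selection analyses (alignment-confidence masking, dN/dS
    outlier exclusion, AIC model selection), and a seeded synthetic
    ortholog-family generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
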