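Package: geomex
Title: Structured Attribute Extraction from GEO Sample Metadata with a
    Task-Conditioned Language Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a fixed 15-attribute structured table (cell line, tissue,
    technique, donor characteristics, and related fields) from free-text Gene
    Expression Omnibus (GEO) sample metadata. Sample records are linearized
    into a bracketed key/value text form and attributes are generated one at a
    time by a task-conditioned autoregressive language model, with per-token
    generation probabilities converted into traffic-light confidence classes.
    Includes a small trainable decoder-only transformer backend, input-times-
    gradient saliency maps attributing predictions to input tokens, an
    active/online-learning annotation loop with an augmentation store, schema
    integration for Cistrome- and ENCODE-style annotation tables, a synthetic
    GEO-like corpus generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
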