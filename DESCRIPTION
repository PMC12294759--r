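Package: frbinn
Title: Biologically Informed Sparse Neural Networks with Attribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse, biologically informed neural-network classifiers whose
    connectivity is dictated by a gene/pathway/superpathway hierarchy encoded as
    binary mask matrices, and interprets them with Integrated Gradients, layer
    conductance, and a Kernel SHAP approximation of Shapley values. Includes
    attribution post-processing (per-class rankings, composite scores, top-k
    overlap statistics, top-fraction selection with a pluggable gene filter),
    an epidemiological prone/not-prone classification rule for chronic
    inflammatory diseases based on relative risk, hazard ratio, and
    standardized incidence ratio thresholds, and a seeded synthetic-cohort
    generator with planted class-discriminative gene sets for end-to-end
    testing of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
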