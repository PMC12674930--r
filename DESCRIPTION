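Package: nachos
Title: Nested Cross-Validation with Automated Hyperparameter Optimization
    and Fault-Tolerant Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the NACHOS and DACHOS workflows for benchmarking and
    deploying image classifiers on grouped (hierarchical) data: grouped k-fold
    partitioning with leakage auditing, random-search hyperparameter
    optimization, a nested cross-validation engine with variance-quantified
    test-performance reporting, a deployment variant that retrains the
    selected configuration on the full dataset, a manager-worker task
    scheduler with checkpoint-based crash recovery, partition-scheme
    comparison statistics (one-way ANOVA, variance components, Tukey HSD,
    Cohen's d), and a synthetic generator of grouped image datasets with
    controllable class signal and group-level domain shift. Pluggable
    training backends include a deterministic replay backend driven by
    tabulated accuracies and a small reference classifier for desk-scale
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, parallel, jsonlite, png
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
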