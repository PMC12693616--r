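Package: corestress
Title: Core and Stress-Specific Gene Discovery from Multi-Stressor
    Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Meta-analysis toolkit for deriving core (shared across all
    stressors) and stress-specific stress-responsive gene sets from a
    multi-experiment TPM expression compendium. Implements per-experiment
    TN-ratio differential expression calls with union/intersection set
    operations, hold-one-stressor-out random-forest classification with
    SMOTE balancing and importance-based feature selection, empirical-Bayes
    batch adjustment and PCA, weighted co-expression modules with kME hub
    genes, one-sided Fisher/FDR enrichment statistics, and GENIE3-style
    regulatory-network inference with repeated Dunnett comparisons of
    regulatory weights. Includes a synthetic compendium generator with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    ranger,
    stats,
    sva,
    tools,
    utils,
    yaml
Suggests:
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
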