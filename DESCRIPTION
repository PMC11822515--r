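Package: wormtox
Title: Imbalanced-Data QSAR Workflow for Earthworm Reproductive Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for binary QSAR classification of pesticide
    reproductive toxicity in earthworms from imbalanced descriptor data.
    Converts no-observed-effect concentrations (NOEC, mg/kg soil), given as
    real values or intervals, to toxic/nontoxic classes at a 100 mg/kg
    breakpoint; trains under-sampled stochastic gradient-boosted tree
    classifiers tuned by a budgeted Bayesian (Gaussian-process) search;
    selects descriptor subsets with an NSGA-II genetic algorithm over five
    objectives (train/validation Matthews correlation and Brier score plus
    a sparsity penalty); explains predictions with kernel SHAP attributions;
    validates models by Y-scrambling; and stacks two complementary models
    into a dual-threshold applicability domain with a coverage/performance
    threshold scan. Includes a synthetic-data generator emulating the
    statistical structure of pesticide descriptor matrices so the whole
    workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
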