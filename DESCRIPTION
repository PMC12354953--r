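Package: molfewshot
Title: Few-Shot Molecular Property Prediction with a Bayesian Hypernetwork
    Meta-Learner
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Episodic meta-learning for binary molecular property prediction
    in the low-data regime. Molecules are featurized as atom-bond graphs and
    encoded with a graph isomorphism network whose messages carry bond-type
    and bond-direction embeddings. A task-adaptable classifier head is
    specialized per assay by sampling weight deltas from a Gaussian posterior
    emitted by a hypernetwork that reads the support set's embeddings,
    predictions and labels; training minimizes a KL-regularized bi-level
    objective over dynamically resampled class-balanced episodes. Includes a
    gradient-based model-agnostic meta-learning baseline, a synthetic
    motif-driven task-pool generator, and AUROC/PR-AUC/MCC evaluation with
    per-task mean and standard deviation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
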