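Package: dstan
Title: Deep Spatiotemporal Attention Networks for Functional Brain Network Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs functional brain networks from ROI-level fMRI BOLD
    time series (Pearson connectivity with proportional sparsification and
    symmetric normalized adjacency) and classifies mild cognitive impairment
    versus normal controls with a deep spatiotemporal attention network:
    stacked temporal-convolution plus graph-convolution blocks, a per-node
    attention module trained with a mean-minus-variance attention loss, and
    spatiotemporal feature fusion. Includes a synthetic BOLD generator with
    planted connectivity differences, an SGD training loop, stratified
    evaluation with accuracy/sensitivity/specificity, and an attention
    ablation harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'synthetic.R'
    'fbn.R'
    'model.R'
    'backprop.R'
    'loss.R'
    'train.R'
    'evaluate.R'
    'io.R'
    'pipeline.R'
    'dstan-package.R'
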