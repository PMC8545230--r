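Package: squirrelsearch
Title: Squirrel Search Optimization, Wrapper Feature Selection and
    Metaheuristic-Trained Perceptrons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the squirrel search optimization algorithm and its
    advanced variant (ASSOA) as general box-bounded minimizers, together with
    grey wolf optimizer and genetic algorithm baselines, a sigmoid-binarized
    wrapper for feature selection scored by classification error and subset
    size, training of multilayer perceptron connection weights by
    metaheuristic search, synthetic feature-table generators with planted
    structure, and a statistical comparison harness (Wilcoxon rank-sum,
    one-way ANOVA) for benchmarking optimizers across paired runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
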