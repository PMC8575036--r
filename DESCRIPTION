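Package: overlasso
Title: Latent Overlapping Group Lasso for Logistic and Cox Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits logistic and Cox proportional-hazards regression models
    penalized by the latent (overlapping) group lasso, solved by proximal
    gradient descent with block soft-thresholding.  Overlapping variable
    groups are represented through a sparse 0/1 latent expansion map so the
    design matrix is never duplicated column-wise.  Includes regularization
    paths with warm starts, stratified k-fold cross-validation with binomial
    deviance or Harrell's C-index, a simulation-study data generator with
    overlapping adjacent groups, readers and writers for delimited and
    MatrixMarket inputs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    glmnet,
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
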