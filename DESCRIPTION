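Package: templateRL
Title: Reinforcement Learning of Color Attentional Templates with
    Circular Function Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a Q-learning model of attentional-template
    learning on a continuous color wheel. The value of each color is
    represented with von Mises radial basis functions; reward prediction
    errors drive incremental weight updates, and surprising outcomes can
    reset the template. Includes criterion-based task simulation, maximum
    likelihood fitting with BIC model comparison (Reset, No Reset,
    win-stay-lose-forget/shift and dual learning-rate variants),
    generate-and-refit parameter recovery, synthetic neural population
    generation with known tuning, single-neuron encoding model selection,
    pseudo-population decoding with cross-template generalization,
    trial-by-trial circular template readout, and value-representation
    geometry (split-half reliability, correlation disattenuation, PCA
    effective dimensionality, multidimensional scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    lhs,
    e1071,
    nnet,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
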