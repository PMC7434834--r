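Package: sctrnnpb
Title: Stochastic Continuous-Time Recurrent Networks with Parametric Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits stochastic continuous-time recurrent neural networks with
    parametric bias (S-CTRNNPB): hierarchical predictive-coding networks that
    learn to predict both the mean and the variance (uncertainty) of their
    next sensory input by minimizing precision-weighted prediction error via
    backpropagation through time.  The package provides a synthetic generator
    of two-class periodic visuomotor sequences, tools for manipulating the
    heterogeneity of intrinsic neuronal excitability (the neuron-to-neuron
    variance of fixed context-neuron biases), real-time intention inference
    by sliding-window parametric-bias adaptation, and evaluation statistics
    (Kullback-Leibler similarity scores, overfitting and variance-estimation
    metrics, parametric-bias error maps, synaptic weight distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
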