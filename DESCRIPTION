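Package: rssrm
Title: Spectral Spike Response Models with Regularized Parameter Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits single-neuron spike response models to simulated
    membrane-potential recordings and benchmarks them under aggressive
    parameter pruning. Provides a deterministic Izhikevich simulator for
    the twenty canonical firing behaviors, design-matrix builders for
    lagged, Fourier-feature, raised-cosine and principal-component
    regressions, penalized least-squares fitting with L1 pruning to a
    target coefficient count, quantile/local-maximum spike detection with
    tolerance matching, and RMSE, van Rossum distance and spike-timing
    F1 evaluation, together with a benchmark harness that compares the
    six model families across all behaviors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
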