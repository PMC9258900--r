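Package: pwdistill
Title: Pairwise and Independent Model Distillation for Generative Protein Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains small generative models of aligned protein families (an
    autoregressive model with exact likelihood and a one-hidden-layer
    variational autoencoder) and distills them into pairwise (Potts) and
    independent (profile) energy models by minimizing the mean squared error
    in energies under a chosen sequence distribution (uniform or the model's
    own).  Provides exact enumeration oracles (least-squares minimizer,
    zero-sum Moebius expansion), gauge transformations, stochastic-gradient
    extraction with uniform mixing and EMA-based early stopping, and
    evaluation utilities: range-normalized energy RMSE on
    Hamming-distance-stratified test sets, mutational-effect Spearman
    correlations, coupling comparison in the zero-sum gauge, and
    APC-corrected contact prediction.  Includes planted-model synthetic data
    generators (pairwise, independent, pure three-body) so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
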