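Package: reportuq
Title: Uncertainty Quality of Text Classifiers Under Labeller Disagreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well probabilistic text classifiers
    represent predictive uncertainty when two automatic rule-based labellers
    disagree. Provides a synthetic dual-labeller report-corpus generator with
    boundary-localized disagreement, mean-pooled word-embedding features, a
    sparse variational Gaussian-process multiclass classifier (ARD-RBF kernel,
    inducing points, Monte-Carlo evidence lower bound via the
    reparameterisation trick), calibrated random-forest and adversarially
    trained deep-ensemble baselines, and evaluation of negative log predictive
    probability (NLPP) and mean maximum predicted confidence level (MMPCL)
    over consistent and inconsistent label partitions, including group-wise
    false-negative versus true-positive confidence analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
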