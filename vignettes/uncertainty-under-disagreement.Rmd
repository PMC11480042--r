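---
title: "Uncertainty quality under labeller disagreement: models and methods"
author: "reportuq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty quality under labeller disagreement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical text corpora are frequently labelled by automatic rule-based
labellers rather than by physicians. When two such labellers — one more
conservative (emitting more "uncertain" verdicts), one more lenient — are run
over the same radiology reports, they agree on the vast majority of documents
(the *consistent* partition, CONS) and disagree on a small remainder (the
*inconsistent* partition, INCONS) that concentrates on genuinely ambiguous,
borderline reports. Disagreement is therefore a usable proxy for label noise:
a classifier with well-behaved predictive uncertainty should be markedly less
confident on the inconsistent partition, and — because missing a positive
finding is costlier than a false alarm — less confident on its false
negatives than on its true positives.

`reportuq` packages that whole study design: a synthetic dual-labeller corpus
generator (standing in for credentialed hospital data that cannot be
redistributed), mean-pooled word-embedding features, a sparse variational
Gaussian-process (SVGP) classifier built from first principles, calibrated
random-forest and deep-ensemble baselines, and an evaluation layer for the
two uncertainty metrics:

* **NLPP**, the negative log predictive probability
  $-\tfrac1n\sum_i \ln p(y_i \mid x_i)$, which penalizes confident errors and
  under-confident correct predictions alike;
* **MMPCL**, the mean maximum predicted confidence level
  $\tfrac1n\sum_i \max_j p(y_i = C_j \mid x_i)$, a truth-free confidence
  summary that can be compared across groups (e.g. false negatives versus
  true positives).

## The sparse variational GP classifier

Each of the $C = 3$ classes (positive, uncertain, negative) gets an
a-priori independent zero-mean latent function with a shared ARD-RBF kernel

$$k(x, x') = \sigma^2 \exp\Big\{-\tfrac12 \sum_{d} (x_d - x'_d)^2 /
\ell_d^2\Big\},$$

one length scale per embedding dimension, so uninformative directions can be
down-weighted during optimization. The posterior over each latent function is
summarized by $M$ inducing points with a full-covariance Gaussian variational
distribution, trained by maximizing the minibatch evidence lower bound

$$\hat{\mathcal L} = \frac{N}{|B|} \sum_{i \in B}
\hat{\mathbb E}_{q}\big[\log p(y_i \mid f_i)\big] \;-\;
\mathrm{KL}\big(q(u) \,\|\, p(u)\big),$$

where the expected log likelihood is estimated by the reparameterisation
trick: the marginal latent at each point is $f = \mu + \sqrt{v}\,\varepsilon$
with $\varepsilon \sim N(0,1)$, so the Monte-Carlo average is differentiable
in all parameters. Training uses RMSProp (learning rate 0.003, batch size
500 by default, matching the study protocol this mirrors).

Design choices that the method description leaves open, resolved here:

* **Inverse link.** The multiclass likelihood is a softmax over the $C$
  latent functions (the common choice compatible with a Monte-Carlo ELBO;
  robust-max is the acknowledged alternative). Class probabilities at
  prediction time are the MC expectation of the softmax over the latent
  marginals, with a fixed prediction seed (`mc_train = 20`,
  `mc_predict = 100` by default — a variance/compute trade-off, both
  configurable).
* **Whitened parameterisation.** The variational distribution is expressed
  over whitened inducing values $v = L_{MM}^{-1} u$, making the prior
  standard normal, the KL kernel-independent in closed form, and every
  parameter setting a valid covariance. Variational factors store their
  diagonal in log space so positivity is unconstrained.
* **Gradients.** All gradients (variational means, Cholesky factors, log
  signal variance, log length scales) are analytic; the package contains a
  finite-difference cross-check in its test suite. Kernel hyperparameters
  are shared across the three latent functions (configurable in principle;
  fewer parameters at embedding dimensionality is the sensible default).
* **Inducing inputs** are fixed at k-means centroids of the training
  features rather than optimized: this removes $M \times d$ parameters whose
  gradients would dominate the cost at desk scale, is standard practice, and
  whether the original protocol optimized them is unstated. `M` defaults to
  300 (the protocol value) and is capped at $n$.
* **Epochs.** Two epochs at batch 500 are meaningful for a ~60k corpus but
  give almost no updates on small synthetic corpora, so the default epoch
  count is `max(2, ceiling(200 / updates_per_epoch))`.
* **Numerics.** Cholesky factorizations use an escalating jitter ladder
  (initial `1e-8`, ×10 per failure, capped, logged). Latent variances are
  floored at `1e-12`. Probabilities are floored at `1e-12` before any
  logarithm (shared with the evaluation layer) so NLPP stays finite; floor
  hits are reported. Argmax ties break toward the lower class index and are
  counted.

Two exact relations anchor correctness and are verified in the tests: the
closed-form whitened KL agrees with numerical quadrature, and with a
Gaussian likelihood, inducing points at the data, and the closed-form
optimal variational parameters, the ELBO collapses to the exact GP log
marginal likelihood (the Titsias collapse).

## Baselines

**Calibrated random forest.** A probability forest (`ranger`, 300 trees,
maximum depth 40) trained on primary labels. Raw class frequencies are
post-processed per class by one-vs-rest isotonic regression fitted on the
*validation* split (never the training data, avoiding leakage) and
renormalized to the simplex; a class missing from the calibration data keeps
its raw scores with a warning. Isotonic maps are monotone, so within-class
score order is never reversed. Other tree hyperparameters stay at library
defaults and are recorded in the run manifest.

**Deep ensemble.** Five independently initialized MLPs (three hidden layers
of 200 units with batch normalization), Adam at $3\times10^{-3}$, ten
epochs, with adversarial training: each minibatch loss averages the clean
cross-entropy and the cross-entropy at the fast-gradient-sign perturbation
$x + \epsilon\,\mathrm{sign}(\nabla_x \mathcal{L})$. The FGSM step size is
unstated in the protocol; the default here is $\epsilon = 0.01 \times$ the
per-feature interquartile range, scaling the perturbation to the input range
as deep-ensembles practice recommends. The networks are implemented with
explicit forward/backward passes because adversarial training needs the loss
gradient with respect to the *inputs*, which off-the-shelf R fitters do not
expose; batch-norm inference uses running statistics updated on clean
batches only. The ensemble predictive distribution is the arithmetic mean of
member distributions, which guarantees (Jensen) that ensemble NLPP never
exceeds the mean member NLPP.

## The synthetic corpus generator

The generator defines the study conditions; it is not a tuning knob. Each
report carries a latent severity $s \sim U(0,1)$ mapped to the three ordered
classes by two thresholds placed to reproduce the consistent-partition class
proportions (defaults $0.417 / 0.186 / 0.398$ for positive / uncertain /
negative, from the counts 26,455 / 11,781 / 25,246). Token material comes
from four groups — affirmative disease mentions, negation cues, hedging
terms, neutral filler — with document length Poisson around a mean of 43.5
tokens (truncated at 3). Within-class signal strength varies continuously
with severity (e.g. weak positives near the class boundary carry fewer
affirmative tokens and an occasional hedge), so boundary documents are
genuinely harder, which is exactly the structure the uncertainty analysis
presupposes.

Both labellers are deterministic pure functions of the token list: count
hedging tokens; neutralize affirmative tokens within `negation_scope` tokens
after a negation cue; verdict "uncertain" if the hedging count reaches
`hedging_threshold`, else "positive" if non-neutralized affirmative evidence
remains, else "negative". The primary (conservative) rule uses threshold 2
and scope 2; the secondary uses threshold 3 and scope 1. Disagreement arises
only from deliberately ambiguous token patterns — a hedge count between the
two thresholds, or a negation-affirmative gap that defeats only the narrower
scope — and these patterns are assigned only to documents whose severity
lies within `boundary_width` (default 0.025) of a class threshold, at a rate
calibrated to hit the corpus-level disagreement target (default 4%). An
unreachable target raises a configuration error naming both parameters.

Two honesty notes. First, with threshold rules sharing one hedge count, a
disagreement in which the *secondary* labeller says "uncertain" is
structurally impossible (a hedge count reaching the higher threshold reaches
the lower one too); the generator therefore reproduces the qualitative skew
of real labeller pairs (the conservative labeller dominates the "uncertain"
verdicts among disagreements; the lenient one mostly answers "negative",
sometimes "positive") but not the full mixture observed in real data.
Second, the latent severity is persisted for diagnostics only; no model
stage may consume it — features are a function of tokens and the embedding
table alone.

The embedding fixture draws one vector per token from a fixed-seed isotropic
Gaussian and offsets the three signal groups along mutually orthogonal
directions so mean-pooled documents are linearly separable in expectation.
Dimension defaults to 32 at desk scale; any table in word2vec text format
(including real 200-dimensional biomedical vectors) can be substituted via
`read_embeddings()`. Out-of-vocabulary tokens are skipped with
renormalization; an all-OOV document maps to the zero vector and the event
is logged — the least-assumption policy for a question the protocol leaves
open.

## Partitioning and evaluation protocol

Splits are stratified by the primary label (the training target) with
largest-remainder rounding, 10% validation and 10% test, repeated (default
twice) with derived seeds; headline metrics are arithmetic means over the
repeats, and every raw per-repeat value is retained in the report. Within
the test partition, agreeing reports form the consistent pool and
disagreeing reports one id set evaluated twice: against the secondary labels
(`NegINCONSTest`) and against the primary labels (`CheXINCONSTest`). A
consistent subsample size-matched to the inconsistent set (`CONSTest`) is
the comparison point for accuracy/NLPP, controlling for set size. The
group-wise FN/TP confidence analysis is computed on the *full* consistent
test partition (`CONSFull`): at desk scale the size-matched subsample holds
only a few dozen documents and its FN groups are routinely empty. Empty
groups are always reported as explicit markers with their counts, never
silently zero. The asymmetric-risk analysis covers the positive and
uncertain classes and ignores the negative class, whose false negatives are
not the costly error.

The reliability analysis (equal-width binning of maximum probability,
expected calibration error $\sum_b \frac{n_b}{n}\,|acc_b - conf_b|$, 10 bins
by default) is a standard stand-in for a calibration appendix whose exact
methodology is not available; it is used to verify that isotonic calibration
helps the forest on held-out synthetic reports.

## Reproducibility and problem sizes

Every stochastic stage derives its seed from the single global seed plus a
stage tag, and `run_experiment()` writes a manifest (resolved configuration
plus all derived seeds) before computing anything; `run_from_manifest()`
re-executes a run and reproduces all report files bit-identically. The
desk-scale preset (`paper_analog_config()`) uses 10,000 reports, 32-d
embeddings, 96 inducing points, and two repeated splits — sized so a full
three-model run completes in minutes on one CPU while preserving the
qualitative phenomena of interest: higher NLPP on both inconsistent variants
than on the matched consistent subsample, and lower GP confidence on
positive-class false negatives than true positives.

What passing on synthetic data does and does not show: it validates the
machinery (model correctness, metric exactness, the direction of the
disagreement and asymmetric-risk effects under boundary-localized label
noise) but not the magnitudes reported on real credentialed clinical data,
whose vocabulary, report structure, labeller rule bases and class overlap
are far richer than the generator emulates. The generator has no
multi-pathology structure, no discourse or section structure, and a small
vocabulary; its labellers are caricatures keyed to token counts.

## Known limitations

* Single RBF-ARD kernel; no Matern or convolutional kernels, no deep-kernel
  features.
* Variational posterior is a single full-covariance Gaussian per latent
  function (no mixtures).
* No decision-boundary or referral-threshold selection; metrics are
  reported, not thresholded into actions.
* The secondary labeller never answers "uncertain" on disagreements (see
  above), so the inconsistent partition's label mixture is a simplification.
* Isotonic calibration is fitted one-vs-rest and renormalized; with three
  classes this is standard but not a proper multiclass calibration method.
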