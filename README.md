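# reportuq

Uncertainty quality of probabilistic text classifiers under automatic
labeller disagreement.

## What this package is for

Large clinical text corpora are usually labelled by automatic rule-based
labellers, not by physicians. Run two different labellers — one conservative
(many "uncertain" verdicts), one lenient — over the same radiology reports
and they will agree on ~96% of documents and disagree on a small remainder
concentrated on genuinely borderline reports. That disagreement is a free
probe of label noise: a classifier whose predictive uncertainty is
trustworthy should be much less confident where the labellers disagreed, and
less confident on its false negatives (the costly error in medicine) than on
its true positives.

`reportuq` implements that whole study as a reusable, seeded pipeline for
three-class (positive / uncertain / negative) report classification:

* a **synthetic dual-labeller corpus generator** — three ordered classes
  driven by a latent severity, token-level evidence (affirmative, negation,
  hedging, filler groups), two deterministic rule labellers of different
  conservativeness whose disagreement (~4% of documents) occurs only near
  class boundaries — standing in for credentialed hospital data;
* **mean-pooled word-embedding features** (word2vec text format; a synthetic
  fixture table ships with the package);
* a **sparse variational Gaussian-process classifier** written from first
  principles: ARD-RBF kernel, inducing points, whitened full-covariance
  variational posterior, closed-form KL, Monte-Carlo expected softmax
  likelihood via the reparameterisation trick, RMSProp training with fully
  analytic gradients;
* two baselines: an isotonic-**calibrated random forest** (via `ranger`) and
  a **deep ensemble** of five batch-normalized MLPs with FGSM adversarial
  training (hand-written backprop, which exposes the input gradient FGSM
  needs);
* an **evaluation layer**: accuracy, NLPP
  $-\tfrac1n\sum_i \ln p(y_i\mid x_i)$, MMPCL
  $\tfrac1n\sum_i\max_j p(y_i{=}C_j\mid x_i)$, group-wise FN/TP confidence
  for the positive and uncertain classes, reliability diagrams with expected
  calibration error, all averaged over repeated stratified splits.

Test sets come in three variants: `NegINCONSTest` and `CheXINCONSTest` — the
same disagreeing reports judged against the lenient and the conservative
labeller respectively — and `CONSTest`, a size-matched subsample of the
agreeing reports.

## Worked example

```r
library(reportuq)

corpus <- generate_corpus(n = 2000, seed = 42)
corpus
#> labelled_corpus: 2000 reports, disagreement 0.039, mean length 43.5 tokens

round(corpus_stats(corpus)$primary_proportions, 3)
#>  positive uncertain  negative
#>     0.395     0.198     0.406

table  <- synthetic_embeddings(dimension = 32)
X      <- featurize_corpus(corpus, table)
labels <- setNames(corpus$reports$primary_label, corpus$reports$report_id)

split    <- make_split(corpus, seed = 1)
variants <- make_test_variants(corpus, split, seed = 2)
gp <- fit_svgp(X[split$train_ids, ], labels[split$train_ids],
               num_inducing = 64, batch_size = 200, seed = 1)

pd <- predict(gp, X[variants$incons_ids, ])
nlpp(pd$probs, variants$neg_incons_truth)        # 0.941
nlpp(predict(gp, X[variants$cons_subsample_ids, ])$probs,
     variants$cons_subsample_truth)              # 0.635
mmpcl(pd$probs)                                  # 0.523
```

The numbers are the point: on the reports where the labellers disagreed the
GP's negative log predictive probability is substantially higher (0.94 vs
0.64) and its mean maximum confidence substantially lower (0.52 vs 0.62)
than on the size-matched consistent subsample — the model knows where the
labels are unreliable.

`run_experiment(experiment_config(seed = 1))` runs the full protocol (all
three models, two repeated splits) and returns per-model reports plus
combined summary tables; with `out_dir` set it writes a manifest first and
every artifact beneath it, and `run_from_manifest()` reproduces the run
bit-identically.

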