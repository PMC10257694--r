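---
title: "Validating DIA peak groups with generalizable precursor scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating DIA peak groups with generalizable precursor scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In data-independent acquisition (DIA) mass spectrometry, every precursor in
a spectral library is hunted for in every run, and each candidate
chromatographic peak group is described by a vector of quality subscores.
Statistical validation must decide which target peak groups are genuine and
control the false discovery rate (FDR) against matched decoys. The dominant
approach retrains a semi-supervised classifier per experiment. That works
when the library matches the sample, but in discovery settings — undepleted
plasma searched against a full tissue library, proteogenomic searches, and
similar — the search space dwarfs the sample's true proteome. Most "target"
labels are then wrong, classifier training destabilizes, and FDR estimates
drift.

`diascore` takes the opposite route: train a high-precision precursor
classifier once, on curated data, and apply it unchanged to new samples. The
classifier both scores peak groups (a discriminant "d-score") and *predicts*
which targets are real; the prediction gates the search space before FDR
estimation, so the decoy-based error model is not swamped by false targets.
No incorrect-target (pi0) estimation is used anywhere — identifications are
gained by removing false targets, not by down-weighting decoys.

## Label denoising

Training labels in target/decoy data are inherently noisy: a target peak
group is labeled positive whether or not the peptide is present. The
denoiser removes these noisy positives per sample:

1. Split the sample's target precursors into *k* folds (default 10).
2. For each fold, train an ensemble of *n* bagged logistic-regression
   members (default 10) on the remaining targets (label 1) plus **all**
   decoys (label 0). Each member sees an independent bootstrap resample of
   the partition, the same size as the partition — the standard bagging
   contract; the bootstrap's own statistics standardize the features.
3. The ensemble votes on the held-out fold. A member's vote is positive
   when its predicted probability is at least `vote_probability`
   (default 0.75, boundary inclusive).
4. A target is kept only if the positive-vote fraction reaches
   `required_vote_fraction` (default 1.0 — unanimity).

Decoys are never filtered: they remain the complete negative class for
training and the yardstick for FDR estimation. Members are fitted by
stochastic gradient descent on the logistic loss with L2 regularization;
probabilities are raw logistic outputs, deliberately uncalibrated — the
0.75 threshold is defined on exactly these values. The threshold trades a
little true-target recall for strict exclusion of false positives, which is
the correct trade for *training-set* curation (the lost targets are still
scored later; nothing is lost from the analysis itself).

## Classifiers

Two flavours share one interface and one stored feature scaler
(per-feature center/scale estimated on the pooled training set):

* `svm` — a linear hinge-loss model fitted by stochastic gradient descent
  (L2 penalty, `alpha = 1e-5`, adaptive learning-rate schedule, early
  stopping on a 10% validation split). The SGD kernel is implemented in
  C++ with its own deterministic generator so fits are bit-reproducible.
* `gbt` — gradient-boosted trees (xgboost) with a raw-logit objective and
  log-loss as the evaluation metric; depth 6, learning rate 0.1, up to 200
  rounds with early stopping after 20 stalled rounds. The raw-logit
  objective keeps the output an unsquashed margin.

Both receive the class-imbalance ratio `n_decoys / n_targets` as a
positive-class weight, so a mismatch-heavy pool cannot let the majority
class dominate. The d-score is the raw decision margin, not a probability:
margins preserve the bimodal target/decoy score geometry that the density
estimation below depends on, whereas the logistic squashing compresses
exactly the tails where thresholds live. For *predictions*, the margin is
mapped through the logistic link and thresholded at `probability_threshold`
(default 0.5, the symmetric point of the link; the threshold is exposed in
the configuration for stricter or looser gating).

Gating keeps predicted-true targets **plus every decoy**. Discarding
high-scoring decoys would bias the error model; they are needed to measure
how often a null feature vector scores well.

## q-values

Two estimators are provided and are required (by test) to agree:

* **Counting.** At target score $s$, with $D(s)$ decoys and $T(s)$ targets
  scoring at least $s$, the raw FDR is $D/(T+D)$; a record's q-value is the
  minimum raw FDR over all thresholds at or below its score. Ties share one
  value. Note the denominator: this package uses $D/(T+D)$ throughout —
  the fraction of the accepted set expected to be false — rather than the
  classical $D/T$.
* **Spline.** A smoothed version for annotating scores not in the fitted
  set: the empirical CDF of each class is evaluated on a 1,000-point grid
  spanning the pooled score range padded by three bin widths, and a
  monotone-preserving cubic interpolant (`monoH.FC`) is fitted in
  cumulative space. Fitting the CDF rather than the density guarantees
  non-negative densities and exact tail areas; tail counts are
  `count * (1 - CDF(s))`. The stored density (the interpolant's
  derivative) is normalized to unit trapezoid integral for presentation;
  q-values use the CDF directly. Scores outside the grid are clamped to
  the grid edge. The spline path requires at least 50 scores per class and
  falls back to counting below that.

Global peptide/protein control selects, per group key, the best-scoring
record across all samples and re-estimates q-values on those
representatives. Protein groups are opaque strings; no protein inference is
attempted.

## The quantitative matrix and its evaluations

A cell enters the matrix only if that sample's record passes the
precursor-level q cutoff; a row survives only if its peptide and protein
pass their global cutoffs. Missing cells stay missing — zero imputation is
a modeling decision that belongs downstream.

Two evaluation designs are built in. *Entrapment*: when a species known to
be absent is included in the search space, its identification rate at each
q threshold is an empirical FDR; calibration means this rate stays near the
nominal value. *Ratio validation*: in a two-group spike-in, a precursor is
validated when its between-group log2 fold change falls within a tolerance
(default ±0.2) of its species' expected ratio. Group means are taken on the
raw intensity scale and then logged; the alternative (mean of logs) is a
defensible choice, but raw-scale means match how spike-in benchmarks are
usually read. The "FDR" curve over widening tolerance windows is
implemented as the out-of-window fraction among rows with a computable
ratio — the plausible alternative (decoy-derived FDR within the window)
answers a different question and is deliberately not conflated with it.
Rows entirely absent from one group are excluded from ratio statistics and
counted separately.

## The simulator

All tests and the acceptance script run on simulated experiments, because
the package's claims are statistical properties (calibration, robustness,
monotonicity), and those need ground truth:

* Subscores are 22-dimensional Gaussians with exchangeable correlation 0.3.
  True targets are shifted by `effect_size` (default 3 standard deviations)
  on 12 designated informative features; false targets and decoys share the
  null exactly. A `null_shift` parameter can displace the null to emulate a
  scoring environment unlike the training one.
* `true_target_fraction` models search-space mismatch: 0.5 mimics a
  matched library, 0.05 the plasma-versus-tissue-library regime where
  fewer than one target in twenty is real.
* Identity structure (precursor/peptide/protein keys, species, base
  retention time, base abundance) is fixed across samples; subscores and
  intensities are redrawn per sample. Intensities follow a two-group log2
  design with Gaussian noise and missing-at-random dropout.
* One master seed drives everything through per-sample derived streams, so
  output is bit-reproducible.

The simulator is a fixture, not a physical model: it has no
retention-time drift, no correlated (informative) missingness, no
interference between co-eluting peptides, and its subscore covariance is
far tidier than OpenSWATH's real output. Passing tests therefore
demonstrate that the algorithms do what they claim under their stated
assumptions — not that any particular real dataset will reach the same
numbers.

## Problem sizes and tolerances

The shipped checks use: a 30-sample matched-library experiment (5,000
targets at 30% true plus 5,000 decoys per sample; 20 samples for
denoise/train, 10 held out) for FDR calibration, in which the realized
false-discovery proportion at q ≤ 0.01 must land in [0.003, 0.03]; a
balanced-to-5% transfer experiment for gating (≥ 90% false-target removal,
≥ 95% true-target retention, FDP ≤ 0.03); 10,000 scores per class for
spline/counting agreement (max gap ≤ 0.01 where q ≤ 0.1); a six-sample
two-species entrapment design (entrapment FDR ≤ 1.5× nominal at q ∈
{0.01, 0.02, 0.05, 0.1}); and a 2×10-replicate spike-in with log2 noise
0.1 (≥ 95% ratio-validated at ±0.2, exact log2FC = 2 in the noise-free
limit). These sizes were chosen as the smallest at which the binomial noise
on each criterion is comfortably below its tolerance.

## Known limitations

* Denoising is strictly per sample; no cross-sample pooling of votes.
* The second-pass re-extraction that a full workflow would perform after
  retention-time anchoring is out of scope; gating operates on already
  extracted tables, and `build_rt_library()` only exports the anchors.
* The spline q-value estimator assumes enough decoys to shape the null
  (≥ 50); tiny experiments silently use counting instead.
* Differential expression, normalization, and protein quantification are
  intentionally absent — the matrix is the hand-off point to dedicated
  downstream tooling.

## A minimal run

```{r example}
library(diascore)

res <- run_pipeline(
  list(simulation = list(n_samples = 6, n_targets = 2000, n_decoys = 2000)),
  out_dir = "validation_run", seed = 1
)
res$model
res$matrix
```

The artifact directory contains the serialized classifier, per-sample
scored tables, global peptide/protein models, the quantitative matrix, and
a manifest of md5 checksums; rerunning with the same config and seed
reproduces every file byte for byte.
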