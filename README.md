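# diascore

Search-space-agnostic statistical validation of data-independent
acquisition (DIA) mass-spectrometry peak groups.

## The problem

DIA identification works by extracting, for every precursor in a spectral
library, candidate chromatographic peak groups described by 22 MS2-level
quality subscores, then separating genuine target matches from noise with a
classifier whose score is calibrated against reversed/shuffled decoys. The
standard tools retrain that classifier per experiment, semi-supervised.
This collapses in discovery settings — undepleted plasma searched against a
repository-scale tissue library, proteogenomic searches — where the library
is far larger than the sample's true proteome: most target labels are then
false, training destabilizes, and FDR control drifts.

`diascore` is built around generalizable precursor scoring: train a
high-precision classifier once on curated data, then apply it unchanged to
any new sample, using its *predictions* to gate false targets out of the
search space before FDR estimation. For users it provides:

- **Label denoising** (`denoise_sample()`): per-sample k-fold bagged
  logistic ensembles vote on every target; only unanimously approved
  targets (member probability ≥ 0.75) survive into training. Decoys are
  never filtered.
- **Classifiers** (`train_classifier()`): a stochastic-gradient linear
  hinge-loss model and gradient-boosted trees (raw-logit objective,
  log-loss metric), both with class-imbalance weights and a stored feature
  scaler.
- **Scoring and gating** (`compute_dscore()`, `predict_targets()`,
  `build_rt_library()`): d-scores are raw decision margins; gating keeps
  predicted-true targets plus *all* decoys.
- **FDR control** (`qvalues_counting()`, `qvalues_spline()`,
  `global_rollup()`): at score *s* the raw FDR is *D*/(*T*+*D*) over the
  tail counts, monotonized into q-values; the spline variant fits a
  monotone cubic interpolant to the cumulative score distributions on a
  1,000-point grid. Global peptide/protein q-values come from the
  best-scoring representative per group across all runs. No pi0/PIT
  down-weighting anywhere.
- **Quantitative export and evaluation** (`build_matrix()`,
  `missingness()`, `entrapment_curve()`, `ratio_validation()`): an
  annotated precursor × sample matrix plus the two standard benchmarks —
  entrapment FDR from a known-absent species, and spike-in ratio
  validation against expected log2 fold changes.
- **A ground-truth simulator** (`simulate_experiment()`,
  `simulate_spikein()`): labeled synthetic experiments with controllable
  true-target fraction, effect size, species mixtures and quantitative
  designs, driving every test in the package.

## Worked example

```r
library(diascore)

res <- run_pipeline(
  list(simulation = list(n_samples = 6, n_targets = 2000, n_decoys = 2000)),
  out_dir = "validation_run", seed = 1
)
res$model
#> <precursor_model> kind=gbt  features=22  threshold=0.50  trained on 2955 targets / 6000 decoys
res$peptide_model
#> <global_level_model> level=peptide  groups=1749 (1000 decoy)  q-method=spline
res$matrix
#> <quant_matrix> 988 precursors x 3 samples, 0.5% missing
```

The pipeline simulated six samples of 2,000 targets (half of them true)
plus 2,000 decoys, denoised and pooled the first three samples (5,910
records of which 2,955 denoised targets), trained the boosted-tree
classifier, scored the held-out three samples with prediction gating, and
assembled the q-filtered quantitative matrix: 988 precursors that pass the
1% precursor, peptide and protein cutoffs, with 0.5% missing cells. The
artifact directory holds the serialized models, scored TSVs, the matrix
and an md5 manifest; rerunning with the same seed reproduces every file
byte for byte.

A thin command-line wrapper over the same functions ships in
`inst/cli/diascore.R` (subcommands `simulate`, `denoise`, `train`, `score`,
`rt-library`, `combine`, `matrix`, `run`).

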