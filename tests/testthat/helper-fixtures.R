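# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk.

library(data.table)

# Small simulated experiment with package defaults scaled down.
tiny_sim <- function(n_samples = 1L, n_targets = 400L, pi = 0.5,
                     n_decoys = 400L, effect = 3, seed = 1L, ...) {
  simulate_experiment(simulation_config(
    n_samples = n_samples, n_targets = n_targets,
    true_target_fraction = pi, n_decoys = n_decoys,
    effect_size = effect, seed = seed, ...
  ))
}

# Hand-specifiable linear model: identity scaler, known weights/bias, so
# dscore = x %*% weights + bias can be verified by hand.
toy_linear_model <- function(weights, bias = 0, threshold = 0.5) {
  w <- rep(0, 22)
  w[seq_along(weights)] <- weights
  structure(
    list(model_kind = "svm",
         params = list(weights = w, bias = bias, epochs = 1L),
         scaler = list(center = rep(0, 22), scale = rep(1, 22)),
         feature_names = peakgroup_features(),
         probability_threshold = threshold,
         provenance = list(note = "hand-built test model")),
    class = "precursor_model"
  )
}

# Vote ensemble whose members emit fixed probabilities for every record
# (weights 0, bias = qlogis(p)), used to pin down the voting rules.
stub_ensemble <- function(probs) {
  members <- lapply(probs, function(p) {
    list(weights = rep(0, 22), bias = qlogis(p),
         center = rep(0, 22), scale = rep(1, 22))
  })
  structure(list(members = members, seed = 0L), class = "vote_ensemble")
}

# Minimal hand-built peak-group table: features are null draws; ids simple.
toy_table <- function(n_targets = 6L, n_decoys = 4L, seed = 1L,
                      sample_id = "s1") {
  set.seed(seed)
  n <- n_targets + n_decoys
  feats <- matrix(rnorm(n * 22), n, 22,
                  dimnames = list(NULL, peakgroup_features()))
  dt <- data.table(
    sample_id = sample_id,
    precursor_id = sprintf("prec%03d", seq_len(n)),
    peakgroup_rank = 1L,
    peptide_id = sprintf("pep%03d", (seq_len(n) - 1L) %/% 2L + 1L),
    protein_group = sprintf("prot%02d", (seq_len(n) - 1L) %/% 4L + 1L),
    decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys)),
    retention_time = seq(0, 1000, length.out = n),
    intensity = 2^rnorm(n, 20, 1)
  )
  as_peakgroup_table(cbind(dt, as.data.table(feats)))
}

# Plain data.frame view of a peak-group table, shorn of diagnostic
# attributes, for record-level identity comparisons.
plain_df <- function(tab) {
  df <- as.data.frame(tab)
  attr(df, "denoise_votes") <- NULL
  df
}

# Score a sample, keep best peak groups, attach counting q-values.
score_and_q <- function(model, sample) {
  best <- select_best_peakgroup(compute_dscore(model, sample))
  q <- qvalues_counting(best[decoy == FALSE, dscore],
                        best[decoy == TRUE, dscore])
  best[, qvalue_precursor := NA_real_]
  best[decoy == FALSE, qvalue_precursor := q]
  best
}
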