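#' Compute discriminant scores for a sample
#'
#' Applies a fitted [train_classifier()] model to a peak-group table. The
#' discriminant score is the untransformed decision margin (linear margin or
#' raw tree logit) after applying the model's stored feature scaler; margins,
#' unlike squashed probabilities, preserve the bimodal target/decoy score
#' geometry the q-value density fit relies on. No records are dropped.
#'
#' @param model A `precursor_model`.
#' @param table A `peakgroup_table` whose features match the model.
#' @return The table with a `dscore` column added.
#' @export
compute_dscore <- function(model, table) {
  table <- as_peakgroup_table(table)
  x <- pg_feature_matrix(table, model$feature_names)
  out <- copy(table)
  out[, dscore := model_margin(model, x)]
  as_peakgroup_table(out)
}

#' Predict true precursors and gate the search space
#'
#' Flags records whose logistic-mapped discriminant score reaches the
#' probability threshold as predicted true targets, and returns the gated
#' subset used for downstream FDR estimation: predicted-true targets plus
#' *all* decoys. Decoys are never removed by gating — however high they
#' score — because the decoy distribution is the yardstick for the FDR.
#'
#' @param model A `precursor_model`.
#' @param table A scored `peakgroup_table`.
#' @param threshold Probability threshold (default: the model's).
#' @return List with `scored` (full table with `predicted_target` flags) and
#'   `gated` (predicted-true targets + all decoys).
#' @export
predict_targets <- function(model, table, threshold = NULL) {
  table <- as_peakgroup_table(table)
  if (!is_scored(table)) {
    abort_diascore("not_scored", "predict_targets() needs a scored table")
  }
  threshold <- threshold %||% model$probability_threshold
  out <- copy(table)
  out[, predicted_target := plogis(dscore) >= threshold]
  gated <- out[predicted_target | decoy]
  list(scored = as_peakgroup_table(out), gated = as_peakgroup_table(gated))
}

#' Select retention-time anchor precursors
#'
#' Partitions the observed retention-time range of the predicted-true targets
#' into `num_bins` equal-width bins and keeps, per non-empty bin, the single
#' highest-scoring record (ties broken by lowest `peakgroup_rank`, then input
#' order). The result is a compact sample-specific retention-time anchor
#' library for re-alignment.
#'
#' @param table A scored table carrying `predicted_target` flags.
#' @param num_bins Number of equal-width retention-time bins (>= 1).
#' @return `data.table` with `precursor_id`, `retention_time`, `dscore`,
#'   `bin`; at most `num_bins` rows.
#' @export
build_rt_library <- function(table, num_bins = 10L) {
  table <- as_peakgroup_table(table)
  stopifnot(num_bins >= 1L)
  if (!"predicted_target" %in% names(table)) {
    abort_diascore("not_scored", "build_rt_library() needs predicted_target flags")
  }
  cand <- table[predicted_target == TRUE & decoy == FALSE]
  if (nrow(cand) == 0L) {
    abort_diascore("empty_selection", "no predicted-true targets to select from")
  }
  rng <- range(cand$retention_time)
  breaks <- seq(rng[1], rng[2], length.out = num_bins + 1L)
  cand <- copy(cand)
  cand[, `..ord` := .I]
  cand[, bin := pmin(num_bins, pmax(1L, findInterval(
    retention_time, breaks, rightmost.closed = TRUE
  )))]
  setorder(cand, bin, -dscore, peakgroup_rank, `..ord`)
  anchors <- cand[, .SD[1L], by = bin,
                  .SDcols = c("precursor_id", "retention_time", "dscore")]
  setcolorder(anchors, c("precursor_id", "retention_time", "dscore", "bin"))
  anchors[]
}
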