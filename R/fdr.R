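#' Decoy-counting q-values
#'
#' The direct empirical estimator. At each target score `s` the raw false
#' discovery rate is `D / (T + D)` where `D` is the number of decoy scores
#' `>= s` and `T` the number of target scores `>= s`; the q-value of a record is
#' the minimum raw FDR over all thresholds at or below its score, so q-values
#' are monotone non-increasing in score. Tied scores share one value. No
#' incorrect-target (pi0) down-weighting is applied anywhere in this package:
#' identifications are boosted by prediction gating instead.
#'
#' @param target_scores Numeric vector of target discriminant scores.
#' @param decoy_scores Numeric vector of decoy discriminant scores.
#' @return Numeric q-values aligned with `target_scores`.
#' @export
#' @examples
#' qvalues_counting(c(3, 2, 1), 1.5) # 0, 0, 0.25
qvalues_counting <- function(target_scores, decoy_scores) {
  if (length(target_scores) == 0L) {
    abort_diascore("empty_input", "no target scores")
  }
  if (length(decoy_scores) == 0L) return(rep(0, length(target_scores)))
  ord <- order(target_scores, decreasing = TRUE)
  s <- target_scores[ord]
  # counts of decoys/targets >= s via sorted lookup
  d_sorted <- sort(decoy_scores)
  n_d <- length(d_sorted)
  D <- n_d - findInterval(s, d_sorted, left.open = TRUE)
  T_ <- seq_along(s)
  # tied target scores share the count at the lowest position of the tie
  T_ <- ave(T_, s, FUN = max)
  raw <- D / (T_ + D)
  # q(s) = min raw FDR over thresholds <= s, i.e. the suffix minimum in
  # decreasing-score order; this makes q monotone non-increasing in score
  q <- rev(cummin(rev(raw)))
  out <- numeric(length(s))
  out[ord] <- q
  pmin(pmax(out, 0), 1)
}

#' Fit smoothed target/decoy score distributions
#'
#' Builds a shared score grid spanning the pooled score range (padded by
#' three bin widths on each side) and fits a monotone-preserving cubic
#' interpolant to the cumulative empirical distribution of each class.
#' Densities are the (non-negative) derivatives of the interpolated CDFs,
#' normalized to unit trapezoid integral over the grid. Fitting in cumulative
#' space guarantees non-negative densities and exact tail areas.
#'
#' @param target_scores,decoy_scores Numeric score vectors (>= 50 each).
#' @param grid_size Number of grid points (default 1000).
#' @return A `score_distribution` object.
#' @export
fit_score_distributions <- function(target_scores, decoy_scores,
                                    grid_size = 1000L) {
  if (length(target_scores) < 50L || length(decoy_scores) < 50L) {
    abort_diascore("too_few_records",
                   "need at least 50 scores per class to fit densities")
  }
  pooled <- c(target_scores, decoy_scores)
  rng <- range(pooled)
  h <- diff(rng) / grid_size
  if (h == 0) h <- 1e-6
  grid <- seq(rng[1] - 3 * h, rng[2] + 3 * h, length.out = grid_size)

  fit_class <- function(scores) {
    s <- sort(scores)
    cdf <- findInterval(grid, s) / length(s)
    f <- splinefun(grid, cdf, method = "monoH.FC")
    dens <- pmax(0, f(grid, deriv = 1))
    area <- trapezoid(grid, dens)
    list(cdf = cdf, density = if (area > 0) dens / area else dens)
  }
  t_fit <- fit_class(target_scores)
  d_fit <- fit_class(decoy_scores)

  structure(
    list(score_grid = grid,
         target_density = t_fit$density, decoy_density = d_fit$density,
         target_cdf = t_fit$cdf, decoy_cdf = d_fit$cdf,
         target_count = length(target_scores),
         decoy_count = length(decoy_scores)),
    class = "score_distribution"
  )
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

# Interpolated CDF value(s) at arbitrary scores; out-of-grid scores are
# clamped to the grid edge.
dist_cdf <- function(dist, scores, class = c("target", "decoy")) {
  class <- match.arg(class)
  cdf <- if (class == "target") dist$target_cdf else dist$decoy_cdf
  s <- pmin(pmax(scores, dist$score_grid[1]),
            dist$score_grid[length(dist$score_grid)])
  f <- splinefun(dist$score_grid, cdf, method = "monoH.FC")
  pmin(1, pmax(0, f(s)))
}

#' Spline-density q-values
#'
#' Evaluates q-values from a fitted [fit_score_distributions()] object. At
#' score `s`, the decoy tail count is `decoy_count * (1 - F_decoy(s))` and
#' the target tail count `target_count * (1 - F_target(s))`, where the `F`s
#' are the monotone interpolated CDFs; the raw FDR is the decoy tail divided
#' by the total tail, and each record's q-value is the minimum raw FDR over
#' thresholds at or below its score, clipped to `[0, 1]`. Scores outside the grid are clamped
#' to the grid edge.
#'
#' @param dist A `score_distribution`.
#' @param scores Scores at which to evaluate q-values.
#' @return Numeric q-values aligned with `scores`.
#' @export
qvalues_spline <- function(dist, scores) {
  stopifnot(inherits(dist, "score_distribution"))
  if (length(scores) == 0L) return(numeric(0))
  D <- dist$decoy_count * (1 - dist_cdf(dist, scores, "decoy"))
  T_ <- dist$target_count * (1 - dist_cdf(dist, scores, "target"))
  raw <- ifelse(T_ + D > 0, D / (T_ + D), 0)
  ord <- order(scores, decreasing = TRUE)
  q <- numeric(length(scores))
  q[ord] <- rev(cummin(rev(raw[ord])))  # suffix min over lower thresholds
  pmin(pmax(q, 0), 1)
}

#' Fit a reusable score-to-q-value mapping
#'
#' Convenience wrapper choosing the spline path when both classes have at
#' least `min_spline` scores and falling back to decoy counting otherwise.
#' The returned object maps arbitrary future scores to q-values.
#'
#' @param target_scores,decoy_scores Numeric score vectors.
#' @param method `"auto"`, `"spline"` or `"counting"`.
#' @param min_spline Minimum per-class count for the spline path.
#' @return A `qvalue_fit` object; evaluate with [qvalue_at()].
#' @export
fit_qvalue_map <- function(target_scores, decoy_scores,
                           method = c("auto", "spline", "counting"),
                           min_spline = 50L) {
  method <- match.arg(method)
  if (length(target_scores) == 0L) {
    abort_diascore("empty_input", "no target scores")
  }
  use_spline <- switch(
    method,
    spline = TRUE,
    counting = FALSE,
    auto = length(target_scores) >= min_spline &&
      length(decoy_scores) >= min_spline
  )
  if (use_spline) {
    dist <- fit_score_distributions(target_scores, decoy_scores)
    q <- qvalues_spline(dist, target_scores)
  } else {
    dist <- NULL
    q <- qvalues_counting(target_scores, decoy_scores)
  }
  # step mapping for annotating new scores: q at the largest known score <= s
  ord <- order(target_scores)
  structure(
    list(method = if (use_spline) "spline" else "counting",
         dist = dist,
         knot_scores = target_scores[ord], knot_q = q[ord],
         decoy_scores = sort(decoy_scores)),
    class = "qvalue_fit"
  )
}

#' Evaluate a fitted q-value mapping at new scores
#'
#' @param fit A [fit_qvalue_map()] object.
#' @param scores Numeric scores.
#' @return q-values in `[0, 1]`, monotone non-increasing in score.
#' @export
qvalue_at <- function(fit, scores) {
  stopifnot(inherits(fit, "qvalue_fit"))
  if (!is.null(fit$dist)) return(qvalues_spline(fit$dist, scores))
  idx <- findInterval(scores, fit$knot_scores)
  q <- ifelse(idx == 0L, 1, fit$knot_q[pmax(idx, 1L)])
  pmin(pmax(q, 0), 1)
}

#' Roll scores up to the global peptide or protein level
#'
#' Aggregates all scored samples in an experiment, selects per group key
#' (`peptide_id` or `protein_group`) the highest-scoring representative
#' record across samples, and estimates q-values on the representative
#' target scores against the representative decoy scores (spline path when
#' counts allow, decoy counting otherwise). Protein groups are opaque keys;
#' no protein inference is performed.
#'
#' @param samples List of scored `peakgroup_table`s, best-peakgroup selection
#'   already applied.
#' @param level `"peptide"` or `"protein"`.
#' @return A `global_level_model`: the per-group best-score/q table plus the
#'   fitted score-to-q mapping for annotating future scores.
#' @export
global_rollup <- function(samples, level = c("peptide", "protein")) {
  level <- match.arg(level)
  if (!length(samples)) abort_diascore("empty_input", "no samples to roll up")
  key_col <- if (level == "peptide") "peptide_id" else "protein_group"
  pooled <- rbindlist(lapply(samples, function(s) {
    s <- as_peakgroup_table(s)
    if (!is_scored(s)) abort_diascore("not_scored", "all samples must be scored")
    as.data.table(s)[, .(group_key = get(key_col), dscore, decoy)]
  }))
  if (nrow(pooled) == 0L) abort_diascore("empty_input", "no records to roll up")
  setorder(pooled, group_key, -dscore)
  best <- pooled[, .(best_dscore = dscore[1L], is_decoy = all(decoy)),
                 by = group_key]
  fit <- fit_qvalue_map(best[is_decoy == FALSE, best_dscore],
                        best[is_decoy == TRUE, best_dscore])
  best[, qvalue := qvalue_at(fit, best_dscore)]
  setindex(best, NULL)
  structure(
    list(level = level, table = best[], fit = fit),
    class = "global_level_model"
  )
}

#' @export
print.global_level_model <- function(x, ...) {
  cat(sprintf(
    "<global_level_model> level=%s  groups=%d (%d decoy)  q-method=%s\n",
    x$level, nrow(x$table), sum(x$table$is_decoy), x$fit$method
  ))
  invisible(x)
}
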