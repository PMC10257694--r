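#' Denoising configuration
#'
#' Settings for the per-sample k-fold ensemble-vote denoiser that removes
#' noisy "false target" labels before classifier training. The defaults —
#' ten folds, ten bagged logistic members per fold, a positive-vote
#' probability threshold of 0.75 and a unanimous-vote requirement — are the
#' settings used throughout the package.
#'
#' @param k_folds Number of folds the target precursors are split into
#'   (integer >= 2).
#' @param ensemble_size Number of bagged logistic-regression members trained
#'   per fold (integer >= 1).
#' @param vote_probability A member's vote is positive when its predicted
#'   probability is `>=` this threshold (boundary inclusive).
#' @param required_vote_fraction Fraction of positive votes a target needs to
#'   be kept; `1.0` keeps only unanimously approved targets.
#' @param seed Master seed; fold assignment, bootstrap draws, and SGD
#'   shuffling derive independent streams from it.
#' @return A `denoise_config` list.
#' @export
denoise_config <- function(k_folds = 10L, ensemble_size = 10L,
                           vote_probability = 0.75,
                           required_vote_fraction = 1.0, seed = 1L) {
  stopifnot(k_folds >= 2L, ensemble_size >= 1L,
            vote_probability > 0, vote_probability < 1,
            required_vote_fraction > 0, required_vote_fraction <= 1)
  structure(
    list(k_folds = as.integer(k_folds),
         ensemble_size = as.integer(ensemble_size),
         vote_probability = vote_probability,
         required_vote_fraction = required_vote_fraction,
         seed = as.integer(seed)),
    class = "denoise_config"
  )
}

# Derive a reproducible sub-seed from a master seed; kept < 2^31.
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed)
  for (k in c(...)) x <- (x * 69069 + as.numeric(k) * 2654435761) %% 2147483629
  as.integer(x) + 1L
}

#' Assign cross-validation folds to target records
#'
#' Splits the target (non-decoy) records of a sample into `k` folds whose
#' sizes differ by at most one. Decoys are not folded: they enter every
#' training partition and are never voted on.
#'
#' @param table A `peakgroup_table`.
#' @param k Number of folds.
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return Integer vector of fold labels in `1:k`, one per target record (in
#'   the order targets appear in `table`).
#' @export
assign_folds <- function(table, k = 10L, seed = 1L) {
  table <- as_peakgroup_table(table)
  n_targets <- sum(!table$decoy)
  if (n_targets < k) {
    abort_diascore(
      "too_few_records",
      sprintf("%d target records cannot be split into %d folds", n_targets, k)
    )
  }
  labels <- rep(seq_len(k), length.out = n_targets)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  sample(labels)
}

# Save/restore .Random.seed around a local set.seed().
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Train a bagged ensemble of logistic scorers
#'
#' Fits `n_members` L2-regularized logistic-regression members by stochastic
#' gradient descent, each on an independent bootstrap resample (same size as
#' the partition, drawn with replacement). Features are standardized with
#' each member's own bootstrap statistics; class-imbalance weight
#' `n_negative / n_positive` is applied to the positive class.
#'
#' @param x Numeric feature matrix of the training partition.
#' @param y Integer labels: targets = 1, decoys = 0.
#' @param n_members Ensemble size.
#' @param seed Integer seed.
#' @param alpha L2 regularization strength.
#' @return A `vote_ensemble` object.
#' @export
train_vote_ensemble <- function(x, y, n_members = 10L, seed = 1L,
                                alpha = 1e-5) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    abort_diascore("degenerate_labels",
                   "training partition contains a single class")
  }
  n <- nrow(x)
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    mseed <- derive_seed(seed, 17L, m)
    old <- .Random.seed_guard(mseed)
    idx <- sample.int(n, n, replace = TRUE)
    old()
    xb <- x[idx, , drop = FALSE]
    yb <- y[idx]
    if (length(unique(yb)) < 2L) {
      # resample until both classes present (guaranteed to terminate for
      # two-class partitions; degenerate inputs were rejected above)
      attempt <- 0L
      while (length(unique(yb)) < 2L && attempt < 100L) {
        attempt <- attempt + 1L
        old <- .Random.seed_guard(derive_seed(mseed, attempt))
        idx <- sample.int(n, n, replace = TRUE)
        old()
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
      }
    }
    center <- colMeans(xb)
    scale <- apply(xb, 2L, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    xs <- sweep(sweep(xb, 2L, center), 2L, scale, "/")
    pos_weight <- sum(yb == 0) / max(1L, sum(yb == 1))
    fit <- .sgd_fit(
      xs, yb, loss = 1L, alpha = alpha, pos_weight = pos_weight,
      max_epochs = 30L, eta0 = 0.01, early_stopping = FALSE,
      validation_fraction = 0.1, n_iter_no_change = 5L, tol = 1e-4,
      seed = derive_seed(mseed, 23L)
    )
    members[[m]] <- list(weights = fit$weights, bias = fit$bias,
                         center = center, scale = scale)
  }
  structure(list(members = members, seed = seed), class = "vote_ensemble")
}

member_probability <- function(member, x) {
  xs <- sweep(sweep(x, 2L, member$center), 2L, member$scale, "/")
  plogis(.linear_margin(xs, member$weights, member$bias))
}

#' Ensemble vote on held-out records
#'
#' Each member emits a probability per record; a vote is positive when the
#' probability is `>= vote_probability` (a probability exactly equal to the
#' threshold counts as positive).
#'
#' @param ensemble A [train_vote_ensemble()] fit.
#' @param x Feature matrix of held-out records (disjoint from training).
#' @param vote_probability Positive-vote probability threshold.
#' @return `data.table` with one row per record: `mean_probability` and
#'   `vote_fraction` (share of members voting positive).
#' @export
vote <- function(ensemble, x, vote_probability = 0.75) {
  stopifnot(inherits(ensemble, "vote_ensemble"))
  x <- as.matrix(x)
  probs <- vapply(ensemble$members, member_probability, numeric(nrow(x)), x = x)
  probs <- matrix(probs, nrow = nrow(x))
  data.table(
    mean_probability = rowMeans(probs),
    vote_fraction = rowMeans(probs >= vote_probability)
  )
}

#' Denoise a sample's target labels by k-fold ensemble voting
#'
#' Target precursors are split into `k_folds` folds; each fold is voted on by
#' a bagged logistic ensemble trained on the remaining targets plus all
#' decoys, so no record is scored by a model that saw it. Targets whose
#' positive-vote fraction reaches `required_vote_fraction` are kept; decoys
#' pass through unfiltered and unchanged — they remain the negative class for
#' downstream training and FDR estimation.
#'
#' @param table A `peakgroup_table` containing both targets and decoys.
#' @param config A [denoise_config()].
#' @return The filtered `peakgroup_table` (original row order, records
#'   untouched), with the per-target vote table in attribute
#'   `"denoise_votes"`.
#' @export
denoise_sample <- function(table, config = denoise_config()) {
  table <- as_peakgroup_table(table)
  stopifnot(inherits(config, "denoise_config"))
  if (!any(table$decoy) || !any(!table$decoy)) {
    abort_diascore("degenerate_labels",
                   "denoising needs both target and decoy records")
  }
  x <- pg_feature_matrix(table)
  target_rows <- which(!table$decoy)
  decoy_rows <- which(table$decoy)
  folds <- assign_folds(table, k = config$k_folds,
                        seed = derive_seed(config$seed, 1L))

  vote_fraction <- rep(NA_real_, length(target_rows))
  mean_probability <- rep(NA_real_, length(target_rows))
  for (f in seq_len(config$k_folds)) {
    held <- folds == f
    train_rows <- c(target_rows[!held], decoy_rows)
    y <- c(rep(1L, sum(!held)), rep(0L, length(decoy_rows)))
    ens <- train_vote_ensemble(
      x[train_rows, , drop = FALSE], y,
      n_members = config$ensemble_size,
      seed = derive_seed(config$seed, 2L, f)
    )
    v <- vote(ens, x[target_rows[held], , drop = FALSE],
              vote_probability = config$vote_probability)
    vote_fraction[held] <- v$vote_fraction
    mean_probability[held] <- v$mean_probability
  }

  keep_target <- vote_fraction >= config$required_vote_fraction
  keep <- rep(TRUE, nrow(table))
  keep[target_rows] <- keep_target
  out <- as_peakgroup_table(table[keep])
  setattr(out, "denoise_votes", data.table(
    row = target_rows, fold = folds,
    mean_probability = mean_probability,
    vote_fraction = vote_fraction, kept = keep_target
  ))
  out
}
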