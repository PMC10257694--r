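#' Classifier training configuration
#'
#' Settings for the two generalizable precursor classifier flavours: a linear
#' hinge-loss model fitted by stochastic gradient descent (`"svm"`) and
#' gradient-boosted trees (`"gbt"`, raw-logit objective with log-loss as the
#' evaluation metric). Both receive the target:decoy class-imbalance ratio as
#' a positive-class weight.
#'
#' @param model_kind `"gbt"` or `"svm"`.
#' @param l2_alpha L2 regularization strength for the SVM.
#' @param early_stopping Hold out `validation_fraction` of the pool and stop
#'   when the validation objective stalls.
#' @param validation_fraction Fraction of the pool used for early stopping.
#' @param max_epochs Maximum SGD epochs (SVM).
#' @param gbt_max_depth,gbt_nrounds,gbt_eta,gbt_early_stopping_rounds
#'   Gradient-boosted-tree hyperparameters.
#' @param probability_threshold Decision threshold applied to the
#'   logistic-mapped margin when predicting true targets.
#' @param seed Integer seed.
#' @return A `training_config` list.
#' @export
training_config <- function(model_kind = c("gbt", "svm"), l2_alpha = 1e-5,
                            early_stopping = TRUE, validation_fraction = 0.1,
                            max_epochs = 100L, gbt_max_depth = 6L,
                            gbt_nrounds = 200L, gbt_eta = 0.1,
                            gbt_early_stopping_rounds = 20L,
                            probability_threshold = 0.5, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(l2_alpha > 0, validation_fraction > 0, validation_fraction < 1,
            probability_threshold > 0, probability_threshold < 1)
  structure(
    list(model_kind = model_kind, l2_alpha = l2_alpha,
         early_stopping = isTRUE(early_stopping),
         validation_fraction = validation_fraction,
         max_epochs = as.integer(max_epochs),
         gbt_max_depth = as.integer(gbt_max_depth),
         gbt_nrounds = as.integer(gbt_nrounds), gbt_eta = gbt_eta,
         gbt_early_stopping_rounds = as.integer(gbt_early_stopping_rounds),
         probability_threshold = probability_threshold,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Pool per-sample tables into one training set
#'
#' Row-binds denoised (or raw) sample tables into a single labeled pool
#' (targets = 1, decoys = 0) with subscore columns in canonical order. All
#' tables must expose the same feature set.
#'
#' @param tables List of `peakgroup_table`s.
#' @return A pooled `peakgroup_table`; attribute `"class_counts"` holds the
#'   target/decoy counts.
#' @export
assemble_training_set <- function(tables) {
  if (!length(tables)) abort_diascore("empty_input", "no tables to pool")
  feats <- peakgroup_features()
  tables <- lapply(tables, function(t) {
    missing <- setdiff(feats, names(t))
    if (length(missing)) {
      abort_diascore(
        "schema_mismatch",
        sprintf("table lacks feature column(s): %s",
                paste(missing, collapse = ", "))
      )
    }
    as_peakgroup_table(t)
  })
  pool <- rbindlist(tables, use.names = TRUE, fill = TRUE)
  pool <- as_peakgroup_table(pool)
  setattr(pool, "class_counts",
          c(targets = sum(!pool$decoy), decoys = sum(pool$decoy)))
  pool
}

#' Train a generalizable precursor classifier
#'
#' Fits the configured model on a pooled labeled set. A per-feature
#' center/scale transform is estimated on the pool and stored with the model;
#' the positive class receives weight `n_decoys / n_targets`. Training is
#' reproducible: the same pool, config and seed give an identical serialized
#' model.
#'
#' @param pool A pooled `peakgroup_table` (see [assemble_training_set()]).
#' @param config A [training_config()].
#' @return A `precursor_model`.
#' @export
train_classifier <- function(pool, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  pool <- as_peakgroup_table(pool)
  y <- as.integer(!pool$decoy)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_diascore("degenerate_labels", "pool must contain both classes")
  }
  if (n_pos < 100L || n_neg < 100L) {
    abort_diascore("too_few_records",
                   "need at least 100 records per class to train")
  }
  x <- pg_feature_matrix(pool)
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  pos_weight <- n_neg / n_pos

  if (config$model_kind == "svm") {
    fit <- .sgd_fit(
      xs, y, loss = 0L, alpha = config$l2_alpha, pos_weight = pos_weight,
      max_epochs = config$max_epochs, eta0 = 0.01,
      early_stopping = config$early_stopping,
      validation_fraction = config$validation_fraction,
      n_iter_no_change = 5L, tol = 1e-4,
      seed = derive_seed(config$seed, 101L)
    )
    params <- list(weights = as.numeric(fit$weights), bias = fit$bias,
                   epochs = fit$epochs)
  } else {
    old <- .Random.seed_guard(derive_seed(config$seed, 202L))
    on.exit(old(), add = TRUE)
    n <- nrow(xs)
    val_idx <- if (config$early_stopping) {
      sample.int(n, max(1L, floor(config$validation_fraction * n)))
    } else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)
    dtrain <- xgboost::xgb.DMatrix(xs[train_idx, , drop = FALSE],
                                   label = y[train_idx], nthread = 1)
    evals <- list()
    if (length(val_idx)) {
      evals <- list(validation = xgboost::xgb.DMatrix(
        xs[val_idx, , drop = FALSE], label = y[val_idx], nthread = 1))
    }
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logitraw", eval_metric = "logloss",
                    max_depth = config$gbt_max_depth, eta = config$gbt_eta,
                    scale_pos_weight = pos_weight, nthread = 1,
                    seed = derive_seed(config$seed, 203L)),
      data = dtrain, nrounds = config$gbt_nrounds, evals = evals,
      early_stopping_rounds = if (length(evals))
        config$gbt_early_stopping_rounds else NULL,
      verbose = 0
    )
    params <- list(raw = xgboost::xgb.save.raw(booster, raw_format = "ubj"))
  }

  structure(
    list(
      model_kind = config$model_kind,
      params = params,
      scaler = list(center = as.numeric(center), scale = as.numeric(scale)),
      feature_names = peakgroup_features(),
      probability_threshold = config$probability_threshold,
      provenance = list(
        n_targets = n_pos, n_decoys = n_neg, pos_weight = pos_weight,
        config = unclass(config), seed = config$seed,
        package_version = as.character(packageVersion("diascore"))
      )
    ),
    class = "precursor_model"
  )
}

# Decision margins for a fitted model on a raw (unscaled) feature matrix.
model_margin <- function(model, x) {
  stopifnot(inherits(model, "precursor_model"))
  if (ncol(x) != length(model$feature_names)) {
    abort_diascore("schema_mismatch", sprintf(
      "model expects %d features, got %d", length(model$feature_names), ncol(x)
    ))
  }
  xs <- sweep(sweep(x, 2L, model$scaler$center), 2L, model$scaler$scale, "/")
  if (model$model_kind == "svm") {
    as.numeric(.linear_margin(xs, model$params$weights, model$params$bias))
  } else {
    booster <- xgboost::xgb.load.raw(model$params$raw)
    as.numeric(predict(booster, xs))
  }
}

#' @export
print.precursor_model <- function(x, ...) {
  cat(sprintf(
    "<precursor_model> kind=%s  features=%d  threshold=%.2f  trained on %d targets / %d decoys\n",
    x$model_kind, length(x$feature_names), x$probability_threshold,
    x$provenance$n_targets, x$provenance$n_decoys
  ))
  invisible(x)
}

#' Precision diagnostics for a classifier
#'
#' Scores a labeled table with the model, thresholds the logistic-mapped
#' margin, and reports the confusion counts and precision. Positive truth is
#' the `truth_label == "true_target"` annotation when present, otherwise
#' `!decoy`.
#'
#' @param model A `precursor_model`.
#' @param table A `peakgroup_table` with truth or decoy labels.
#' @param threshold Probability threshold; defaults to the model's.
#' @return A `precision_report` list: `tp`, `fp`, `tn`, `fn`, `precision`
#'   (`NA` with `undefined = TRUE` when no positive predictions were made).
#' @export
precision_report <- function(model, table, threshold = NULL) {
  table <- as_peakgroup_table(table)
  threshold <- threshold %||% model$probability_threshold
  margin <- model_margin(model, pg_feature_matrix(table, model$feature_names))
  pred <- plogis(margin) >= threshold
  truth <- if ("truth_label" %in% names(table) && !anyNA(table$truth_label)) {
    table$truth_label == "true_target"
  } else {
    !table$decoy
  }
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         precision = precision, undefined = tp + fp == 0L),
    class = "precision_report"
  )
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report> tp=%d fp=%d tn=%d fn=%d precision=%s\n",
              x$tp, x$fp, x$tn, x$fn,
              if (x$undefined) "undefined" else sprintf("%.4f", x$precision)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
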