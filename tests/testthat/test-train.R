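test_that("training pools tables and validates schemas", {
  t1 <- toy_table(n_targets = 60L, n_decoys = 40L, seed = 1, sample_id = "a")
  t2 <- toy_table(n_targets = 60L, n_decoys = 40L, seed = 2, sample_id = "b")
  pool <- assemble_training_set(list(t1, t2))
  expect_equal(nrow(pool), 200L)
  expect_equal(attr(pool, "class_counts"),
               c(targets = 120L, decoys = 80L))

  # permuted subscore column order is canonicalized
  perm <- setcolorder(copy(t2), rev(names(t2)))
  pool2 <- assemble_training_set(list(t1, perm))
  expect_equal(pg_feature_matrix(pool), pg_feature_matrix(pool2))

  broken <- copy(t2)[, var_yseries_score := NULL]
  expect_error(assemble_training_set(list(t1, broken)),
               class = "diascore_schema_mismatch")
})

test_that("both classifier flavours reach high held-out precision", {
  sim <- tiny_sim(n_samples = 2L, n_targets = 800L, pi = 0.5,
                  n_decoys = 800L, seed = 41)
  pool <- assemble_training_set(
    lapply(sim$samples[1L], denoise_sample, config = denoise_config(seed = 3L))
  )
  held <- sim$samples[[2L]]
  for (kind in c("svm", "gbt")) {
    model <- train_classifier(pool, training_config(kind, seed = 5L))
    rep <- precision_report(model, held)
    expect_gte(rep$precision, 0.98)
  }
})

test_that("class weighting keeps recall stable under 1:20 imbalance", {
  balanced <- tiny_sim(n_targets = 500L, pi = 1, n_decoys = 500L, seed = 42)
  imbal <- tiny_sim(n_targets = 150L, pi = 1, n_decoys = 3000L, seed = 43)
  held <- tiny_sim(n_targets = 500L, pi = 1, n_decoys = 500L, seed = 44)$samples[[1L]]
  recall <- vapply(list(balanced, imbal), function(s) {
    model <- train_classifier(s$samples[[1L]], training_config("svm", seed = 6L))
    r <- precision_report(model, held)
    r$tp / (r$tp + r$fn)
  }, numeric(1))
  expect_lte(abs(recall[1L] - recall[2L]), 0.10)
})

test_that("degenerate and undersized pools are rejected", {
  targets_only <- toy_table(n_targets = 150L, n_decoys = 0L)
  expect_error(train_classifier(targets_only),
               class = "diascore_degenerate_labels")
  small <- toy_table(n_targets = 50L, n_decoys = 50L)
  expect_error(train_classifier(small), class = "diascore_too_few_records")
  expect_error(training_config("lda"))
})

test_that("training is deterministic: same pool, config, seed => identical model files", {
  sim <- tiny_sim(n_targets = 300L, pi = 0.5, n_decoys = 300L, seed = 45)
  pool <- sim$samples[[1L]]
  for (kind in c("svm", "gbt")) {
    m1 <- train_classifier(pool, training_config(kind, seed = 8L))
    m2 <- train_classifier(pool, training_config(kind, seed = 8L))
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_precursor_model(m1, f1)
    write_precursor_model(m2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("the scaler absorbs feature rescaling for the linear model", {
  sim <- tiny_sim(n_targets = 400L, pi = 0.5, n_decoys = 400L, seed = 46)
  pool <- sim$samples[[1L]]
  held <- tiny_sim(n_targets = 200L, pi = 0.5, n_decoys = 200L, seed = 47)$samples[[1L]]
  m1 <- train_classifier(pool, training_config("svm", seed = 9L))
  scaled_pool <- copy(pool)[, var_library_corr := var_library_corr * 1000]
  scaled_held <- copy(held)[, var_library_corr := var_library_corr * 1000]
  m2 <- train_classifier(as_peakgroup_table(scaled_pool),
                         training_config("svm", seed = 9L))
  p1 <- compute_dscore(m1, held)$dscore
  p2 <- compute_dscore(m2, as_peakgroup_table(scaled_held))$dscore
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("precision reports count the confusion table correctly", {
  model <- toy_linear_model(weights = 1)  # dscore = first subscore
  tab <- toy_table(n_targets = 100L, n_decoys = 0L, seed = 48)
  # margins: +1 for 90 true and 10 false labeled rows; negative otherwise
  tab[, var_bseries_score := c(rep(1, 100))]
  tab[, truth_label := c(rep("true_target", 90), rep("false_target", 10))]
  rep <- precision_report(model, as_peakgroup_table(tab))
  expect_equal(rep$tp, 90L)
  expect_equal(rep$fp, 10L)
  expect_equal(rep$precision, 0.9)
  expect_false(rep$undefined)

  # no positive predictions => undefined, not zero
  tab[, var_bseries_score := -1]
  rep0 <- precision_report(model, as_peakgroup_table(tab))
  expect_true(rep0$undefined)
  expect_true(is.na(rep0$precision))
})

test_that("model serialization round-trips bit-exactly", {
  sim <- tiny_sim(n_targets = 300L, pi = 0.5, n_decoys = 300L, seed = 49)
  for (kind in c("svm", "gbt")) {
    m <- train_classifier(sim$samples[[1L]], training_config(kind, seed = 2L))
    f <- withr::local_tempfile()
    write_precursor_model(m, f)
    back <- read_precursor_model(f)
    expect_identical(back$scaler, m$scaler)
    expect_identical(back$params[names(back$params) != "epochs"],
                     m$params[names(m$params) != "epochs"])
    f2 <- withr::local_tempfile()
    write_precursor_model(back, f2)
    expect_identical(readLines(f), readLines(f2))
    # and it scores identically
    s <- tiny_sim(n_targets = 100L, pi = 0.5, n_decoys = 100L,
                  seed = 50)$samples[[1L]]
    expect_identical(compute_dscore(m, s)$dscore,
                     compute_dscore(back, s)$dscore)
  }
})
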