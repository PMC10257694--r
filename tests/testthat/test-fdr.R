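test_that("counting q-values match exhaustive hand counts", {
  # at s=1: one decoy >= 1 and three targets >= 1 -> 1/4
  expect_equal(qvalues_counting(c(3, 2, 1), 1.5), c(0, 0, 0.25))
  # ties share one value: both targets at 1, one decoy above -> 1/3
  expect_equal(qvalues_counting(c(1, 1), 2), c(1 / 3, 1 / 3))
  # no decoys -> all zero
  expect_equal(qvalues_counting(c(5, 1), numeric(0)), c(0, 0))
  expect_error(qvalues_counting(numeric(0), 1), class = "diascore_empty_input")
})

test_that("counting q-values agree with a quadratic-time reference", {
  brute <- function(targets, decoys) {
    raw <- vapply(targets, function(s) {
      d <- sum(decoys >= s); t <- sum(targets >= s)
      d / (t + d)
    }, numeric(1))
    # q = min raw FDR over all thresholds at or below the record's score
    vapply(seq_along(targets), function(i) {
      min(raw[targets <= targets[i]])
    }, numeric(1))
  }
  set.seed(77)
  for (rep in 1:20) {
    t <- round(rnorm(40, 1), 2)  # rounding forces ties
    d <- round(rnorm(30), 2)
    expect_equal(qvalues_counting(t, d), brute(t, d))
  }
})

test_that("q-values are monotone non-increasing in score", {
  set.seed(78)
  for (rep in 1:10) {
    t <- rnorm(500, 1.5); d <- rnorm(400)
    q <- qvalues_counting(t, d)
    expect_true(all(q >= 0 & q <= 1))
    ord <- order(t)
    expect_true(all(diff(q[ord]) <= 1e-12))
  }
})

test_that("fitted score densities are normalized and match sample moments", {
  set.seed(79)
  d <- rnorm(10000)
  t <- rnorm(10000, 2)
  dist <- fit_score_distributions(t, d)
  g <- dist$score_grid
  trap <- function(y) sum(diff(g) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(dist$decoy_density), 1, tolerance = 1e-3)
  expect_equal(trap(dist$target_density), 1, tolerance = 1e-3)
  expect_true(all(dist$decoy_density >= 0))
  # first moment of the fitted decoy density (midpoint rule) ~ sample mean 0
  mids <- (head(g, -1) + tail(g, -1)) / 2
  dens_mid <- (head(dist$decoy_density, -1) + tail(dist$decoy_density, -1)) / 2
  expect_lt(abs(sum(mids * dens_mid * diff(g))), 0.05)

  expect_error(fit_score_distributions(rnorm(10), rnorm(10)),
               class = "diascore_too_few_records")
})

test_that("identical target and decoy samples give matching densities", {
  set.seed(80)
  s <- rnorm(5000)
  dist <- fit_score_distributions(s, s)
  expect_lt(max(abs(dist$target_density - dist$decoy_density)), 0.05)
  # full-tail raw FDR at the grid minimum is D / (T + D) with no pi0 factor
  q <- qvalues_spline(dist, min(dist$score_grid))
  expect_equal(q, 5000 / 10000, tolerance = 1e-6)
  # empty tails at the grid maximum
  expect_equal(qvalues_spline(dist, max(dist$score_grid)), 0)
})

test_that("spline and counting q-values agree closely at scale", {
  set.seed(81)
  t <- rnorm(10000, 2); d <- rnorm(10000)
  dist <- fit_score_distributions(t, d)
  qs <- qvalues_spline(dist, t)
  qc <- qvalues_counting(t, d)
  reg <- qc <= 0.1
  expect_gt(sum(reg), 1000L)
  expect_lte(max(abs(qs[reg] - qc[reg])), 0.01)
})

test_that("q-value maps annotate new scores consistently", {
  set.seed(82)
  t <- rnorm(300, 2); d <- rnorm(300)
  fit <- fit_qvalue_map(t, d, method = "counting")
  # at known scores the map reproduces the fitted q-values
  expect_equal(qvalue_at(fit, t), qvalues_counting(t, d))
  # scores above the top knot inherit its q; below the bottom knot -> 1
  expect_equal(qvalue_at(fit, max(t) + 10), min(qvalues_counting(t, d)))
  expect_equal(qvalue_at(fit, min(c(t, d)) - 10), 1)
})

test_that("global rollup selects per-group maxima and calibrated q-values", {
  model <- toy_linear_model(weights = 1)
  tabs <- lapply(1:2, function(i) {
    tab <- toy_table(n_targets = 200L, n_decoys = 200L, seed = 82L + i,
                     sample_id = paste0("s", i))
    compute_dscore(model, tab)
  })
  roll <- global_rollup(tabs, level = "peptide")
  pooled <- rbindlist(lapply(tabs, as.data.table))

  # representative score is the max across samples, checked exhaustively
  for (k in sample(roll$table$group_key, 20L)) {
    expect_equal(roll$table[group_key == k, best_dscore],
                 max(pooled[peptide_id == k, dscore]))
  }
  # decoy groups roll up too and fill the decoy side
  expect_gt(sum(roll$table$is_decoy), 0L)

  # q-values equal the counting oracle on representative scores
  rep_t <- roll$table[is_decoy == FALSE]
  oracle <- qvalues_counting(rep_t$best_dscore,
                             roll$table[is_decoy == TRUE, best_dscore])
  if (roll$fit$method == "spline") {
    expect_lte(max(abs(rep_t$qvalue - oracle)), 0.01)
  } else {
    expect_equal(rep_t$qvalue, oracle)
  }

  expect_error(global_rollup(list()), class = "diascore_empty_input")
})

test_that("global models serialize and round-trip bit-exactly", {
  model <- toy_linear_model(weights = 1)
  tabs <- lapply(1:2, function(i) {
    compute_dscore(model, toy_table(n_targets = 150L, n_decoys = 150L,
                                    seed = 90L + i,
                                    sample_id = paste0("s", i)))
  })
  for (level in c("peptide", "protein")) {
    roll <- global_rollup(tabs, level = level)
    f <- withr::local_tempfile()
    write_global_model(roll, f)
    back <- read_global_model(f)
    expect_equal(as.data.frame(back$table), as.data.frame(roll$table),
                 tolerance = 0)
    probe <- c(-5, 0, 1, 3)
    expect_identical(qvalue_at(back$fit, probe), qvalue_at(roll$fit, probe))
    f2 <- withr::local_tempfile()
    write_global_model(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})
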