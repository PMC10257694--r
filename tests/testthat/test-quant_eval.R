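# Build a small scored dataset with hand-controlled q-values for matrix tests.
quant_fixture <- function(n_prec = 10L, n_samples = 4L, seed = 60L) {
  set.seed(seed)
  samples <- lapply(seq_len(n_samples), function(si) {
    tab <- toy_table(n_targets = n_prec, n_decoys = 4L, seed = seed,
                     sample_id = sprintf("s%d", si))
    tab[, dscore := rnorm(.N)]
    tab[, qvalue_precursor := NA_real_]
    # hand-assigned precursor q-values, varying by sample
    tab[decoy == FALSE,
        qvalue_precursor := round(runif(n_prec, 0, 0.03), 4)]
    as_peakgroup_table(tab)
  })
  roll_p <- global_rollup(samples, "peptide")
  roll_pr <- global_rollup(samples, "protein")
  list(samples = samples, peptide = roll_p, protein = roll_pr)
}

test_that("matrix cells follow the per-sample q filter, brute-force checked", {
  fx <- quant_fixture()
  th <- list(precursor = 0.015, peptide = 1, protein = 1)
  qm <- build_matrix(fx$samples, fx$peptide, fx$protein, thresholds = th)

  pooled <- rbindlist(lapply(fx$samples, as.data.table))[decoy == FALSE]
  for (i in seq_len(nrow(qm$annotations))) {
    pid <- qm$annotations$precursor_id[i]
    for (sid in colnames(qm$intensity)) {
      rec <- pooled[precursor_id == pid & sample_id == sid]
      cell <- qm$intensity[i, sid]
      passes <- nrow(rec) == 1L && rec$qvalue_precursor <= th$precursor
      if (passes) {
        expect_equal(cell, rec$intensity)
      } else {
        expect_true(is.na(cell))
      }
    }
  }
  # every retained row passes in at least one sample
  expect_true(all(rowSums(!is.na(qm$intensity)) >= 1L))
  # decoys never appear
  expect_false(any(grepl("^DECOY", rownames(qm$intensity))))
})

test_that("rows failing global cutoffs are dropped and rebuilds are stable", {
  fx <- quant_fixture()
  # choose a peptide cutoff below some of the fitted global q-values
  qs <- fx$peptide$table[is_decoy == FALSE, qvalue]
  cut <- stats::quantile(qs, 0.5, names = FALSE)
  th <- list(precursor = 1, peptide = cut, protein = 1)
  qm <- build_matrix(fx$samples, fx$peptide, fx$protein, thresholds = th)
  kept_peps <- unique(qm$annotations$peptide_id)
  failing <- fx$peptide$table[is_decoy == FALSE & qvalue > cut, group_key]
  expect_length(intersect(kept_peps, failing), 0L)

  # idempotence: the surviving records all satisfy every threshold, so
  # rebuilding from them changes nothing
  qm2 <- build_matrix(fx$samples, fx$peptide, fx$protein, thresholds = th)
  expect_identical(qm$intensity, qm2$intensity)
  expect_equal(as.data.frame(qm$annotations), as.data.frame(qm2$annotations))

  expect_error(
    build_matrix(fx$samples, fx$peptide, fx$protein,
                 thresholds = list(precursor = 2, peptide = 1, protein = 1)),
    class = "diascore_config"
  )
})

test_that("missingness is the fraction of absent cells", {
  fx <- quant_fixture()
  qm <- build_matrix(fx$samples, fx$peptide, fx$protein,
                     thresholds = list(precursor = 1, peptide = 1, protein = 1))
  expect_equal(missingness(qm), 0)  # every q passes at cutoff 1
  qm$intensity[1:2, 1:2] <- NA_real_
  expect_equal(missingness(qm), 4 / length(qm$intensity))
})

test_that("entrapment FDR counts identifications per threshold", {
  ids <- data.table(
    species_tag = c(rep("mouse", 95), rep("yeast", 5)),
    qvalue = c(rep(0.005, 95), rep(0.005, 5))
  )
  rep <- entrapment_curve(ids, "mouse", thresholds = 0.01)
  expect_equal(rep$identifications_total, 100L)
  expect_equal(rep$entrapment_fdr, 0.05)

  none <- entrapment_curve(ids[species_tag == "mouse"], "mouse", 0.01)
  expect_equal(none$entrapment_fdr, 0)

  empty <- entrapment_curve(ids, "mouse", thresholds = 0.001)
  expect_true(is.na(empty$entrapment_fdr))

  # counts are monotone in the threshold
  set.seed(61)
  ids2 <- data.table(species_tag = sample(c("mouse", "yeast"), 500, TRUE),
                     qvalue = runif(500, 0, 0.2))
  curve <- entrapment_curve(ids2, "mouse", seq(0.01, 0.1, by = 0.01))
  expect_true(!is.unsorted(curve$identifications_total))
  expect_true(!is.unsorted(curve$identifications_entrapment))
})

test_that("ratio validation windows and exclusions work on a hand-built matrix", {
  ann <- data.table(
    precursor_id = sprintf("p%d", 1:4),
    peptide_id = sprintf("pep%d", c(1, 1, 2, 3)),
    protein_group = sprintf("prot%d", c(1, 1, 2, 3)),
    species_tag = c("mouse", "yeast", "yeast", "mouse")
  )
  # rows: mouse lfc 0.1 (ok), yeast lfc 1.7 (outside 0.2, inside 0.35),
  # yeast lfc exactly 2 (ok), mouse absent in group B (excluded)
  m <- rbind(
    c(100, 100, 2^0.1 * 100, 2^0.1 * 100),
    c(100, 100, 2^1.7 * 100, 2^1.7 * 100),
    c(100, 100, 400, 400),
    c(100, 100, NA, NA)
  )
  dimnames(m) <- list(ann$precursor_id, c("a1", "a2", "b1", "b2"))
  qm <- structure(list(intensity = m, annotations = ann,
                       thresholds = list(precursor = 1, peptide = 1, protein = 1)),
                  class = "quant_matrix")
  design <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expected <- c(mouse = 0, yeast = 2)

  rr <- ratio_validation(qm, design, expected, tolerance = 0.2)
  expect_equal(rr$per_precursor$validated, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rr$n_not_quantified, 1L)
  expect_equal(rr$aggregate$precursors, 2L)
  expect_equal(rr$aggregate$n_quantified, 3L)

  rr35 <- ratio_validation(qm, design, expected, tolerance = 0.35)
  expect_true(rr35$per_precursor$validated[2L])

  # the validated-count curve is monotone and out-of-window decreases
  expect_true(!is.unsorted(rr$curve$validated_count))
  expect_true(!is.unsorted(-rr$curve$out_of_window_fraction))
})

test_that("a 4x spike with no noise yields exactly log2FC = 2", {
  sp <- simulate_spikein(n_replicates = 3L, n_targets = 120L, n_decoys = 120L,
                         noise_sd = 0, missing_rate = 0, seed = 63)
  model <- toy_linear_model(weights = rep(1, 12))
  scored <- lapply(sp$samples, score_and_q, model = model)
  qm <- build_matrix(scored, global_rollup(scored, "peptide"),
                     global_rollup(scored, "protein"),
                     thresholds = list(precursor = 1, peptide = 1, protein = 1))
  rr <- ratio_validation(qm, sp$design, expected = c(mouse = 0, yeast = 2))
  yeast <- rr$per_precursor[species_tag == "yeast" & !is.na(log2fc)]
  expect_gt(nrow(yeast), 0L)
  expect_equal(yeast$log2fc, rep(2, nrow(yeast)), tolerance = 1e-9)
  mouse <- rr$per_precursor[species_tag == "mouse" & !is.na(log2fc)]
  expect_equal(mouse$log2fc, rep(0, nrow(mouse)), tolerance = 1e-9)
})
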