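#' Build an annotated quantitative matrix
#'
#' Assembles the precursor-by-sample intensity matrix from per-sample scored
#' and validated tables. A cell is present iff that sample's record passes
#' the precursor-level q-value cutoff; a row survives only if its peptide and
#' protein pass their global cutoffs and at least one cell is present.
#' Decoys are excluded. Missing cells are `NA`, never zero-imputed.
#'
#' @param samples List of best-peakgroup tables carrying `qvalue_precursor`.
#' @param peptide_model,protein_model [global_rollup()] models used for the
#'   global q-value annotations.
#' @param thresholds Named list of q-value cutoffs:
#'   `list(precursor =, peptide =, protein =)`, each in `[0, 1]`.
#' @return A `quant_matrix`: `intensity` (rows = precursors, cols = samples),
#'   `annotations` (`precursor_id`, `peptide_id`, `protein_group`,
#'   `species_tag`, global q-values), and the thresholds used.
#' @export
build_matrix <- function(samples, peptide_model, protein_model,
                         thresholds = list(precursor = 0.01, peptide = 0.01,
                                           protein = 0.01)) {
  stopifnot(inherits(peptide_model, "global_level_model"),
            inherits(protein_model, "global_level_model"))
  for (nm in c("precursor", "peptide", "protein")) {
    t <- thresholds[[nm]]
    if (is.null(t) || t < 0 || t > 1) {
      abort_diascore("config", sprintf("threshold '%s' must be in [0, 1]", nm))
    }
  }
  pooled <- rbindlist(lapply(samples, function(s) {
    s <- as_peakgroup_table(s)
    if (!"qvalue_precursor" %in% names(s)) {
      abort_diascore("not_scored", "samples must carry qvalue_precursor")
    }
    cols <- intersect(
      c("sample_id", "precursor_id", "peptide_id", "protein_group",
        "species_tag", "decoy", "intensity", "qvalue_precursor"),
      names(s)
    )
    as.data.table(s)[, cols, with = FALSE]
  }), use.names = TRUE, fill = TRUE)
  pooled <- pooled[decoy == FALSE]
  if (nrow(pooled) == 0L) abort_diascore("empty_input", "no target records")

  pep <- peptide_model$table[, .(peptide_id = group_key, qvalue_peptide = qvalue)]
  prot <- protein_model$table[, .(protein_group = group_key,
                                  qvalue_protein = qvalue)]
  pooled <- pep[pooled, on = "peptide_id"]
  pooled <- prot[pooled, on = "protein_group"]
  pooled <- pooled[!is.na(qvalue_peptide) & !is.na(qvalue_protein)]
  pooled <- pooled[qvalue_peptide <= thresholds$peptide &
                     qvalue_protein <= thresholds$protein]
  pooled <- pooled[qvalue_precursor <= thresholds$precursor]
  if (nrow(pooled) == 0L) {
    abort_diascore("empty_input", "no records pass the configured thresholds")
  }

  sample_ids <- sort(unique(pooled$sample_id))
  ann_cols <- intersect(c("precursor_id", "peptide_id", "protein_group",
                          "species_tag", "qvalue_peptide", "qvalue_protein"),
                        names(pooled))
  annotations <- unique(pooled[, ann_cols, with = FALSE], by = "precursor_id")
  setorder(annotations, precursor_id)
  m <- matrix(NA_real_, nrow(annotations), length(sample_ids),
              dimnames = list(annotations$precursor_id, sample_ids))
  m[cbind(match(pooled$precursor_id, annotations$precursor_id),
          match(pooled$sample_id, sample_ids))] <- pooled$intensity
  structure(
    list(intensity = m, annotations = annotations[], thresholds = thresholds),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d precursors x %d samples, %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity), 100 * missingness(x)))
  invisible(x)
}

#' Fraction of absent cells in a quantitative matrix
#'
#' @param matrix A [build_matrix()] result.
#' @return Fraction in `[0, 1]` of absent (`NA`) intensity cells.
#' @export
missingness <- function(matrix) {
  stopifnot(inherits(matrix, "quant_matrix"))
  if (length(matrix$intensity) == 0L) {
    abort_diascore("empty_input", "empty quantitative matrix")
  }
  mean(is.na(matrix$intensity))
}

#' Entrapment FDR curve
#'
#' In a two-species design where one species is known to be absent from the
#' sample, every identification of that species is a false positive. For each
#' q-value threshold the entrapment FDR is the number of entrapment-species
#' identifications divided by the total number of identifications passing the
#' threshold.
#'
#' @param results `data.table`/data.frame of validated target identifications
#'   with `species_tag` and a q-value column `qvalue`.
#' @param true_species Species actually present in the sample.
#' @param thresholds Numeric vector of q-value cutoffs.
#' @return `data.table` with, per threshold: `identifications_total`,
#'   `identifications_entrapment`, `entrapment_fdr` (`NA` when no
#'   identifications pass).
#' @export
entrapment_curve <- function(results, true_species,
                             thresholds = c(0.01, 0.02, 0.05, 0.1)) {
  results <- as.data.table(results)
  stopifnot(all(c("species_tag", "qvalue") %in% names(results)))
  if (anyNA(results$species_tag)) {
    abort_diascore("malformed_value", "every identification needs species_tag")
  }
  rbindlist(lapply(thresholds, function(t) {
    pass <- results[qvalue <= t]
    total <- nrow(pass)
    entrap <- sum(pass$species_tag != true_species)
    data.table(
      threshold = t,
      identifications_total = total,
      identifications_entrapment = entrap,
      entrapment_fdr = if (total > 0L) entrap / total else NA_real_
    )
  }))
}

#' Spike-in ratio validation
#'
#' Computes per-precursor log2 fold changes between the two design groups
#' (log2 of the mean of present intensities in group B minus log2 of the mean
#' in group A) and flags a row as ratio-validated when its fold change lies
#' within `tolerance` of the expected value for its species. Rows entirely
#' absent from one group are excluded from ratio statistics and counted
#' separately. Aggregates are reported at precursor level, peptide level (a
#' peptide validates if any of its precursors does) and protein level (any
#' validated peptide), and a curve of validated counts / out-of-window
#' fraction is evaluated on a tolerance grid.
#'
#' @param matrix A [build_matrix()] result with `species_tag` annotations.
#' @param design Named character vector mapping sample_id to group; exactly
#'   two groups. The fold change is `log2(mean(group2) / mean(group1))` with
#'   groups in sorted order.
#' @param expected Named numeric vector mapping species to expected log2 fold
#'   change.
#' @param tolerance Validation window half-width (log2 units).
#' @param tolerance_grid Tolerances at which the validated-count curve is
#'   evaluated.
#' @return A `ratio_report` list: `per_precursor` table, `aggregate` counts,
#'   `curve`, and `n_not_quantified` (rows lacking a group entirely).
#' @export
ratio_validation <- function(matrix, design, expected, tolerance = 0.2,
                             tolerance_grid = seq(0.05, 1, by = 0.05)) {
  stopifnot(inherits(matrix, "quant_matrix"))
  groups <- sort(unique(design))
  if (length(groups) != 2L) {
    abort_diascore("config", "design must define exactly two groups")
  }
  samples <- colnames(matrix$intensity)
  if (!all(samples %in% names(design))) {
    abort_diascore("config", "design must cover every sample column")
  }
  a_cols <- samples[design[samples] == groups[1]]
  b_cols <- samples[design[samples] == groups[2]]
  ann <- matrix$annotations
  if (!"species_tag" %in% names(ann)) {
    abort_diascore("config", "matrix has no species_tag annotations")
  }

  mean_present <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  mean_a <- apply(matrix$intensity[, a_cols, drop = FALSE], 1L, mean_present)
  mean_b <- apply(matrix$intensity[, b_cols, drop = FALSE], 1L, mean_present)
  per <- data.table(
    precursor_id = ann$precursor_id,
    peptide_id = ann$peptide_id,
    protein_group = ann$protein_group,
    species_tag = ann$species_tag,
    log2fc = log2(mean_b) - log2(mean_a),
    expected = unname(expected[ann$species_tag])
  )
  quantified <- !is.na(per$log2fc) & !is.na(per$expected)
  per[, validated := quantified & abs(log2fc - expected) <= tolerance]
  comp <- per[quantified]

  aggregate <- list(
    precursors = sum(comp$validated),
    peptides = length(unique(comp[validated == TRUE, peptide_id])),
    proteins = length(unique(comp[validated == TRUE, protein_group])),
    n_quantified = nrow(comp)
  )
  curve <- rbindlist(lapply(tolerance_grid, function(t) {
    ok <- abs(comp$log2fc - comp$expected) <= t
    data.table(tolerance = t, validated_count = sum(ok),
               out_of_window_fraction = 1 - sum(ok) / nrow(comp))
  }))
  structure(
    list(per_precursor = per[], aggregate = aggregate, curve = curve,
         tolerance = tolerance, n_not_quantified = sum(!quantified)),
    class = "ratio_report"
  )
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf(
    "<ratio_report> %d/%d precursors ratio-validated at +/-%.2f (%d peptides, %d proteins); %d not quantified in both groups\n",
    x$aggregate$precursors, x$aggregate$n_quantified, x$tolerance,
    x$aggregate$peptides, x$aggregate$proteins, x$n_not_quantified
  ))
  invisible(x)
}
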