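#' Canonical MS2 subscore feature names
#'
#' The 22 MS2-level subscores computed during DIA signal extraction
#' (fragment-series matches, library similarity measures, co-elution and
#' cross-correlation shape scores, mass deviation, signal-to-noise, mutual
#' information, and normalized retention-time error). Every classifier in the
#' package consumes exactly these columns, in this order.
#'
#' @return Character vector of length 22.
#' @export
#' @examples
#' peakgroup_features()
peakgroup_features <- function() {
  c(
    "var_bseries_score", "var_dotprod_score", "var_intensity_score",
    "var_isotope_correlation_score", "var_isotope_overlap_score",
    "var_library_corr", "var_library_dotprod", "var_library_manhattan",
    "var_library_rmsd", "var_library_rootmeansquare", "var_library_sangle",
    "var_log_sn_score", "var_manhattan_score", "var_massdev_score",
    "var_massdev_score_weighted", "var_mi_score", "var_mi_weighted_score",
    "var_norm_rt_score", "var_xcorr_coelution", "var_xcorr_coelution_weighted",
    "var_xcorr_shape_weighted", "var_yseries_score"
  )
}

# Mandatory identifier/metadata columns, in canonical output order.
pg_id_columns <- function() {
  c("sample_id", "precursor_id", "peakgroup_rank", "peptide_id",
    "protein_group", "decoy", "retention_time", "intensity")
}

pg_optional_columns <- function() {
  c("dscore", "predicted_target", "qvalue_precursor", "truth_label",
    "species_tag")
}

#' Construct / validate a peak-group table
#'
#' A peak-group table is a `data.table` with one row per candidate peak group:
#' identifiers (`sample_id`, `precursor_id`, `peakgroup_rank`, `peptide_id`,
#' `protein_group`), a logical `decoy` flag, `retention_time` (seconds),
#' `intensity` (arbitrary area units, may be `NA`), the 22 subscore columns of
#' [peakgroup_features()], and optionally `dscore`, `predicted_target`,
#' `qvalue_precursor`, `truth_label` and `species_tag`. Validation enforces
#' the presence of all mandatory columns, finiteness of every subscore, and
#' uniqueness of `(sample_id, precursor_id, peakgroup_rank)`.
#'
#' @param x data.frame-like object with the columns above.
#' @return A validated `peakgroup_table` (a `data.table` subclass).
#' @export
as_peakgroup_table <- function(x) {
  dt <- as.data.table(x)
  feats <- peakgroup_features()
  for (col in c(pg_id_columns(), feats)) {
    if (!col %in% names(dt)) stop_missing_column(col)
  }
  if (is.numeric(dt$decoy)) dt[, decoy := decoy != 0]
  if (!is.logical(dt$decoy)) dt[, decoy := as.logical(decoy)]
  if ("predicted_target" %in% names(dt) && is.numeric(dt$predicted_target)) {
    dt[, predicted_target := predicted_target != 0]
  }
  for (col in feats) {
    v <- dt[[col]]
    if (!is.numeric(v)) abort_diascore(
      "malformed_value", sprintf("subscore column '%s' is not numeric", col)
    )
    bad <- which(!is.finite(v))
    if (length(bad)) stop_malformed_value(col, bad[1L])
  }
  if (nrow(dt) > 0L &&
      anyDuplicated(dt, by = c("sample_id", "precursor_id", "peakgroup_rank"))) {
    abort_diascore(
      "duplicate_key",
      "(sample_id, precursor_id, peakgroup_rank) must be unique within a table"
    )
  }
  setattr(dt, "class", unique(c("peakgroup_table", class(dt))))
  dt[]
}

is_scored <- function(table) {
  "dscore" %in% names(table) && !anyNA(table$dscore)
}

#' Read a peak-group TSV file
#'
#' Reads a tab-separated peak-group score file (UTF-8, `.` decimal separator,
#' empty cell = absent value). The `decoy` column uses the OpenSWATH/PyProphet
#' `{0,1}` convention and is mapped to logical. Unknown extra columns are
#' preserved as annotations.
#'
#' @param path Path to a TSV file with a header row.
#' @return A [as_peakgroup_table()]-validated table, possibly with zero rows.
#' @export
read_peakgroups <- function(path) {
  if (!file.exists(path)) {
    abort_diascore("io", sprintf("file not found: %s", path))
  }
  dt <- fread(
    path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
    colClasses = list(character = intersect(
      c("sample_id", "precursor_id", "peptide_id", "protein_group",
        "truth_label", "species_tag"),
      names(fread(path, sep = "\t", nrows = 0L))
    ))
  )
  if (nrow(dt) == 0L) {
    # header-only file: coerce mandatory numeric columns to the right type
    for (col in c("peakgroup_rank", "retention_time", "intensity",
                  peakgroup_features())) {
      if (col %in% names(dt)) set(dt, j = col, value = numeric(0))
    }
  }
  as_peakgroup_table(dt)
}

#' Write a scored peak-group table to TSV
#'
#' Writes the canonical TSV layout (see [read_peakgroups()]); logical columns
#' are encoded as `{0,1}`, absent values as empty cells. Requires the table to
#' carry discriminant scores.
#'
#' @param table A scored `peakgroup_table` (all `dscore` present).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(table, path) {
  table <- as_peakgroup_table(table)
  if (!is_scored(table)) {
    abort_diascore("not_scored", "table has no complete 'dscore' column")
  }
  write_peakgroups(table, path)
}

#' Write a peak-group table to TSV (scored or not)
#'
#' Same canonical layout as [write_scored()] without requiring discriminant
#' scores; used for simulated and denoised tables that have not been scored
#' yet.
#'
#' @param table A `peakgroup_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peakgroups <- function(table, path) {
  table <- as_peakgroup_table(table)
  out <- copy(table)
  out[, decoy := as.integer(decoy)]
  if ("predicted_target" %in% names(out)) {
    out[, predicted_target := as.integer(predicted_target)]
  }
  cols <- c(pg_id_columns(), peakgroup_features(),
            intersect(pg_optional_columns(), names(out)))
  cols <- c(cols, setdiff(names(out), cols))
  setcolorder(out, cols)
  fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Keep the highest-scoring peak group per precursor
#'
#' For each `(sample_id, precursor_id)` the candidate with maximal `dscore` is
#' retained; ties are broken by lowest `peakgroup_rank`, then input order.
#'
#' @param table A scored `peakgroup_table`.
#' @return A `peakgroup_table` with exactly one row per precursor per sample.
#' @export
select_best_peakgroup <- function(table) {
  table <- as_peakgroup_table(table)
  if (!is_scored(table)) {
    abort_diascore("not_scored", "select_best_peakgroup() needs dscore on all records")
  }
  dt <- copy(table)
  dt[, `..ord` := .I]
  setorder(dt, sample_id, precursor_id, -dscore, peakgroup_rank, `..ord`)
  best <- dt[, .SD[1L], by = .(sample_id, precursor_id)]
  setorder(best, `..ord`)
  best[, `..ord` := NULL]
  as_peakgroup_table(best)
}

# Extract the 22-column feature matrix in canonical order.
pg_feature_matrix <- function(table, feature_names = peakgroup_features()) {
  missing <- setdiff(feature_names, names(table))
  if (length(missing)) {
    abort_diascore(
      "schema_mismatch",
      sprintf("table lacks feature column(s): %s", paste(missing, collapse = ", "))
    )
  }
  as.matrix(as.data.table(table)[, feature_names, with = FALSE])
}
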