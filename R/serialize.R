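#' Write a precursor model to a JSON container
#'
#' Serializes a [train_classifier()] model — kind, scaler arrays, feature
#' names, threshold, provenance and the fitted parameters (linear weights, or
#' the boosted-tree bytes base64-encoded) — to a single JSON file that
#' round-trips bit-exactly through [read_precursor_model()]. The container
#' records no timestamps, so identical models serialize to identical bytes.
#'
#' @param model A `precursor_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_precursor_model <- function(model, path) {
  stopifnot(inherits(model, "precursor_model"))
  payload <- list(
    container = "diascore_precursor_model",
    format_version = 1L,
    model_kind = model$model_kind,
    feature_names = model$feature_names,
    scaler = model$scaler,
    probability_threshold = model$probability_threshold,
    provenance = model$provenance
  )
  if (model$model_kind == "svm") {
    payload$params <- model$params
  } else {
    payload$params <- list(raw_base64 = jsonlite::base64_enc(model$params$raw))
  }
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' Read a precursor model from its JSON container
#'
#' @param path Path written by [write_precursor_model()].
#' @return A `precursor_model`.
#' @export
read_precursor_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$container, "diascore_precursor_model")) {
    abort_diascore("io", sprintf("%s is not a precursor model container", path))
  }
  params <- if (payload$model_kind == "svm") {
    list(weights = as.numeric(payload$params$weights),
         bias = as.numeric(payload$params$bias),
         epochs = as.integer(payload$params$epochs))
  } else {
    list(raw = jsonlite::base64_dec(payload$params$raw_base64))
  }
  structure(
    list(model_kind = payload$model_kind,
         params = params,
         scaler = list(center = as.numeric(payload$scaler$center),
                       scale = as.numeric(payload$scaler$scale)),
         feature_names = as.character(payload$feature_names),
         probability_threshold = as.numeric(payload$probability_threshold),
         provenance = payload$provenance),
    class = "precursor_model"
  )
}

#' Write a global peptide/protein model to JSON
#'
#' Serializes a [global_rollup()] model: the per-group best-score table and
#' the fitted score-to-q mapping (grid, CDFs and counts for the spline path;
#' knots for the counting path). Round-trips bit-exactly.
#'
#' @param model A `global_level_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_global_model <- function(model, path) {
  stopifnot(inherits(model, "global_level_model"))
  fit <- model$fit
  payload <- list(
    container = "diascore_global_model",
    format_version = 1L,
    level = model$level,
    table = as.list(model$table),
    fit = list(
      method = fit$method,
      knot_scores = fit$knot_scores, knot_q = fit$knot_q,
      decoy_scores = fit$decoy_scores,
      dist = if (!is.null(fit$dist)) unclass(fit$dist) else NULL
    )
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' Read a global peptide/protein model from JSON
#'
#' @param path Path written by [write_global_model()].
#' @return A `global_level_model`.
#' @export
read_global_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$container, "diascore_global_model")) {
    abort_diascore("io", sprintf("%s is not a global model container", path))
  }
  dist <- NULL
  if (!is.null(payload$fit$dist)) {
    dist <- structure(
      list(score_grid = as.numeric(payload$fit$dist$score_grid),
           target_density = as.numeric(payload$fit$dist$target_density),
           decoy_density = as.numeric(payload$fit$dist$decoy_density),
           target_cdf = as.numeric(payload$fit$dist$target_cdf),
           decoy_cdf = as.numeric(payload$fit$dist$decoy_cdf),
           target_count = as.integer(payload$fit$dist$target_count),
           decoy_count = as.integer(payload$fit$dist$decoy_count)),
      class = "score_distribution"
    )
  }
  fit <- structure(
    list(method = payload$fit$method, dist = dist,
         knot_scores = as.numeric(payload$fit$knot_scores),
         knot_q = as.numeric(payload$fit$knot_q),
         decoy_scores = as.numeric(payload$fit$decoy_scores)),
    class = "qvalue_fit"
  )
  tab <- as.data.table(payload$table)
  tab[, group_key := as.character(group_key)]
  structure(
    list(level = payload$level, table = tab[], fit = fit),
    class = "global_level_model"
  )
}

#' Write a quantitative matrix as wide TSV
#'
#' Annotation columns first, then one intensity column per sample; absent
#' cells are written as empty fields.
#'
#' @param matrix A [build_matrix()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "quant_matrix"))
  wide <- cbind(matrix$annotations,
                as.data.table(matrix$intensity))
  fwrite(wide, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
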