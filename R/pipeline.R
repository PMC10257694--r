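#' Default pipeline configuration
#'
#' Nested list describing a full run: simulation, denoising, training,
#' scoring/gating, q-value estimation, global rollup and matrix export.
#' Every field can be overridden via `modifyList()`-style partial configs
#' (see [run_pipeline()]); all randomness derives from one seed.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(
      n_samples = 6L, n_targets = 1500L, true_target_fraction = 0.5,
      n_decoys = 1500L, n_peakgroups = 1L, effect_size = 3,
      species_mix = c(main = 1), null_species = character()
    ),
    train_fraction = 0.5,
    denoise = list(k_folds = 10L, ensemble_size = 10L,
                   vote_probability = 0.75, required_vote_fraction = 1.0),
    train = list(model_kind = "gbt"),
    score = list(gate = TRUE, threshold = 0.5),
    thresholds = list(precursor = 0.01, peptide = 0.01, protein = 0.01)
  )
}

#' Run the full validation workflow on a simulated experiment
#'
#' Wires the modules together in workflow order: simulate an experiment,
#' denoise the training samples, pool and train a classifier, score the
#' held-out evaluation samples (optionally gating by predicted true targets),
#' select best peak groups, estimate per-sample precursor q-values, roll up
#' to global peptide and protein models, and export the annotated
#' quantitative matrix. All artifacts are written under `out_dir` together
#' with a machine-readable JSON manifest (config, seed, package version, and
#' md5 checksums of every artifact — no timestamps, so reruns with the same
#' config and seed are byte-identical).
#'
#' @param config Partial configuration merged over
#'   [default_pipeline_config()], or a YAML file path (requires the `yaml`
#'   package).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (overrides the config's).
#' @return Invisibly, a list with the in-memory artifacts (`model`,
#'   `scored`, `peptide_model`, `protein_model`, `matrix`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_diascore("config", "reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_diascore("pipeline", sprintf("stage '%s' failed: %s",
                                         name, conditionMessage(e)))
    })
  }

  sim_args <- cfg$simulation
  sim_args$species_mix <- unlist(sim_args$species_mix)
  sim_args$seed <- derive_seed(cfg$seed, 1L)
  sim <- stage("simulate", do.call(
    simulate_experiment, list(do.call(simulation_config, sim_args))
  ))

  n_train <- max(1L, min(length(sim$samples) - 1L,
                         round(cfg$train_fraction * length(sim$samples))))
  train_idx <- seq_len(n_train)
  eval_idx <- setdiff(seq_along(sim$samples), train_idx)

  dn_cfg <- do.call(denoise_config, c(cfg$denoise,
                                      list(seed = derive_seed(cfg$seed, 2L))))
  denoised <- stage("denoise", lapply(sim$samples[train_idx], denoise_sample,
                                      config = dn_cfg))

  tr_cfg <- do.call(training_config, c(cfg$train,
                                       list(seed = derive_seed(cfg$seed, 3L))))
  pool <- stage("assemble", assemble_training_set(denoised))
  model <- stage("train", train_classifier(pool, tr_cfg))
  write_precursor_model(model, file.path(out_dir, "model.json"))

  scored <- stage("score", lapply(sim$samples[eval_idx], function(s) {
    s <- compute_dscore(model, s)
    if (isTRUE(cfg$score$gate)) {
      s <- predict_targets(model, s, threshold = cfg$score$threshold)$gated
    }
    best <- select_best_peakgroup(s)
    q <- qvalues_counting(best[decoy == FALSE, dscore],
                          best[decoy == TRUE, dscore])
    best[, qvalue_precursor := NA_real_]
    best[decoy == FALSE, qvalue_precursor := q]
    best
  }))
  for (s in scored) {
    write_scored(s, file.path(out_dir, sprintf("%s.scored.tsv",
                                               s$sample_id[1])))
  }

  peptide_model <- stage("rollup_peptide", global_rollup(scored, "peptide"))
  protein_model <- stage("rollup_protein", global_rollup(scored, "protein"))
  write_global_model(peptide_model, file.path(out_dir, "peptide_model.json"))
  write_global_model(protein_model, file.path(out_dir, "protein_model.json"))

  qm <- stage("matrix", build_matrix(scored, peptide_model, protein_model,
                                     thresholds = cfg$thresholds))
  write_quant_matrix(qm, file.path(out_dir, "quant_matrix.tsv"))

  cfg_path <- file.path(out_dir, "config.json")
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(17),
                              null = "null"), cfg_path)
  artifacts <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "diascore",
    version = as.character(packageVersion("diascore")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }),
    counts = list(
      samples_total = length(sim$samples),
      samples_train = n_train,
      samples_scored = length(scored),
      pool_targets = sum(!pool$decoy), pool_decoys = sum(pool$decoy),
      matrix_precursors = nrow(qm$intensity),
      matrix_samples = ncol(qm$intensity)
    )
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17),
                              null = "null"),
             file.path(out_dir, "manifest.json"))

  invisible(list(model = model, scored = scored,
                 peptide_model = peptide_model, protein_model = protein_model,
                 matrix = qm, manifest = manifest, truth = sim$truth,
                 config = cfg))
}
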