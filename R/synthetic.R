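#' Simulation configuration for synthetic peak-group experiments
#'
#' Describes a ground-truth-labeled DIA experiment: per sample, `n_targets`
#' target precursors of which a fraction `true_target_fraction` are true
#' (their subscores are shifted away from the null), the rest are false
#' targets sharing the decoy null exactly, plus `n_decoys` decoy precursors.
#' Subscores are 22-dimensional Gaussians with exchangeable correlation
#' `feature_correlation`; true targets get a standardized mean shift of
#' `effect_size` on `n_informative` designated features. A small
#' `true_target_fraction` (about 0.05) emulates the search-space-mismatch
#' regime where a sample is queried against a far larger library, so fewer
#' than one in twenty extracted targets is really present.
#'
#' Precursor identities (ids, truth labels, species, peptide/protein
#' membership, base retention time and base abundance) are fixed across
#' samples; subscores and intensities are redrawn per sample.
#'
#' @param n_samples Number of samples.
#' @param n_targets Target precursors per sample.
#' @param true_target_fraction Fraction of (non-entrapment) targets that are
#'   true.
#' @param n_decoys Decoy precursors per sample.
#' @param n_peakgroups Candidate peak groups per precursor (rank 1 carries
#'   the precursor's class distribution; higher ranks are null draws).
#' @param effect_size Standardized mean shift of true-target subscores on the
#'   informative features.
#' @param n_informative Number of informative subscore dimensions.
#' @param feature_correlation Exchangeable correlation of the subscores.
#' @param null_shift Mean shift applied to the null (false targets and
#'   decoys) on the informative features; nonzero values emulate a scoring
#'   environment whose null differs from the training one.
#' @param species_mix Named fractions assigning target precursors to species
#'   (must sum to 1).
#' @param null_species Species whose targets are forced to be false targets
#'   (entrapment species with no signal in the sample).
#' @param precursors_per_peptide,peptides_per_protein Grouping used to build
#'   peptide and protein identifiers.
#' @param quant Optional quantitative design, see [quant_design()].
#' @param seed Master seed; each sample draws from an independent derived
#'   stream, so output is bit-reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 1L, n_targets = 1000L,
                              true_target_fraction = 0.5, n_decoys = 1000L,
                              n_peakgroups = 1L, effect_size = 3,
                              n_informative = 12L, feature_correlation = 0.3,
                              null_shift = 0, species_mix = c(main = 1),
                              null_species = character(),
                              precursors_per_peptide = 2L,
                              peptides_per_protein = 4L,
                              quant = NULL, seed = 1L) {
  if (n_samples < 1L || n_targets < 1L || n_decoys < 0L || n_peakgroups < 1L) {
    abort_diascore("config", "sizes must be positive")
  }
  if (true_target_fraction < 0 || true_target_fraction > 1) {
    abort_diascore("config", "true_target_fraction must be in [0, 1]")
  }
  if (abs(sum(species_mix) - 1) > 1e-8) {
    abort_diascore("config", "species_mix fractions must sum to 1")
  }
  if (length(null_species) && !all(null_species %in% names(species_mix))) {
    abort_diascore("config", "null_species must appear in species_mix")
  }
  if (n_informative < 1L || n_informative > 22L) {
    abort_diascore("config", "n_informative must be in 1..22")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_targets = as.integer(n_targets),
         true_target_fraction = true_target_fraction,
         n_decoys = as.integer(n_decoys),
         n_peakgroups = as.integer(n_peakgroups), effect_size = effect_size,
         n_informative = as.integer(n_informative),
         feature_correlation = feature_correlation, null_shift = null_shift,
         species_mix = species_mix, null_species = null_species,
         precursors_per_peptide = as.integer(precursors_per_peptide),
         peptides_per_protein = as.integer(peptides_per_protein),
         quant = quant, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Quantitative design for spike-in simulations
#'
#' Two-group design on the log2 intensity scale: a precursor's cell in group
#' B equals its base abundance plus the expected log2 fold change of its
#' species, with Gaussian noise of `noise_sd` log2 units and
#' missing-at-random dropout at `missing_rate`.
#'
#' @param n_replicates Replicates per group (samples = 2 * n_replicates).
#' @param log2fc Named numeric: expected log2 fold change per species.
#' @param noise_sd Log2-scale intensity noise standard deviation.
#' @param missing_rate Missing-at-random cell dropout probability.
#' @param base_log2_mean,base_log2_sd Distribution of per-precursor base
#'   abundance (log2 units).
#' @return A `quant_design` list.
#' @export
quant_design <- function(n_replicates = 10L, log2fc = c(main = 0),
                         noise_sd = 0.1, missing_rate = 0,
                         base_log2_mean = 20, base_log2_sd = 2) {
  stopifnot(n_replicates >= 1L, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(n_replicates = as.integer(n_replicates), log2fc = log2fc,
         noise_sd = noise_sd, missing_rate = missing_rate,
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd),
    class = "quant_design"
  )
}

# Cholesky factor of the exchangeable-correlation feature covariance.
feature_chol <- function(rho, p = 22L) {
  sigma <- matrix(rho, p, p)
  diag(sigma) <- 1
  chol(sigma)
}

# n draws from the 22-dim Gaussian with mean mu (length 22).
draw_features <- function(n, mu, chol_factor) {
  p <- ncol(chol_factor)
  z <- matrix(rnorm(n * p), n, p) %*% chol_factor
  sweep(z, 2L, mu, "+")
}

#' Simulate a ground-truth-labeled peak-group experiment
#'
#' Generates per-sample peak-group tables under a [simulation_config()]:
#' decoys and false targets are drawn from the shared null subscore
#' distribution, true targets from the shifted distribution, non-best
#' candidate peak groups from the null, and intensities follow the quant
#' design (when present). Fixed seed gives bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `samples` (list of `peakgroup_table`), `truth`
#'   (per-precursor `truth_label`, `species_tag`, expected log2 fold change),
#'   `design` (sample-to-group map, or `NULL` without a quant design) and
#'   `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_guard(derive_seed(config$seed, 7L))
  on.exit(old(), add = TRUE)

  n_t <- config$n_targets
  n_d <- config$n_decoys
  # fixed precursor universe -------------------------------------------------
  species <- sample(names(config$species_mix), n_t, replace = TRUE,
                    prob = config$species_mix)
  is_null_species <- species %in% config$null_species
  is_true <- !is_null_species &
    runif(n_t) < config$true_target_fraction
  pep_idx <- (seq_len(n_t) - 1L) %/% config$precursors_per_peptide + 1L
  prot_idx <- (pep_idx - 1L) %/% config$peptides_per_protein + 1L
  charge <- (seq_len(n_t) - 1L) %% config$precursors_per_peptide + 2L
  target_ids <- data.table(
    precursor_id = sprintf("PEP%05d_%d", pep_idx, charge),
    peptide_id = sprintf("PEP%05d", pep_idx),
    protein_group = sprintf("PROT%04d_%s", prot_idx, species),
    species_tag = species, decoy = FALSE,
    truth_label = ifelse(is_true, "true_target", "false_target"),
    base_rt = runif(n_t, 0, 3600),
    base_log2 = if (!is.null(config$quant)) {
      rnorm(n_t, config$quant$base_log2_mean, config$quant$base_log2_sd)
    } else rnorm(n_t, 20, 2)
  )
  decoy_ids <- if (n_d > 0L) {
    dpep <- (seq_len(n_d) - 1L) %/% config$precursors_per_peptide + 1L
    dprot <- (dpep - 1L) %/% config$peptides_per_protein + 1L
    dcharge <- (seq_len(n_d) - 1L) %% config$precursors_per_peptide + 2L
    data.table(
      precursor_id = sprintf("DECOY_PEP%05d_%d", dpep, dcharge),
      peptide_id = sprintf("DECOY_PEP%05d", dpep),
      protein_group = sprintf("DECOY_PROT%04d", dprot),
      species_tag = NA_character_, decoy = TRUE, truth_label = "decoy",
      base_rt = runif(n_d, 0, 3600), base_log2 = rnorm(n_d, 20, 2)
    )
  } else NULL
  universe <- rbindlist(list(target_ids, decoy_ids), use.names = TRUE)

  mu_true <- c(rep(config$effect_size, config$n_informative),
               rep(0, 22L - config$n_informative))
  mu_null <- c(rep(config$null_shift, config$n_informative),
               rep(0, 22L - config$n_informative))
  chol_factor <- feature_chol(config$feature_correlation)

  quant <- config$quant
  design <- NULL
  if (!is.null(quant)) {
    n_samples <- 2L * quant$n_replicates
    if (config$n_samples != n_samples) {
      config$n_samples <- n_samples
    }
    design <- stats::setNames(
      rep(c("A", "B"), each = quant$n_replicates),
      sprintf("sample_%02d", seq_len(n_samples))
    )
  }

  samples <- vector("list", config$n_samples)
  for (si in seq_len(config$n_samples)) {
    sold <- .Random.seed_guard(derive_seed(config$seed, 11L, si))
    sample_id <- sprintf("sample_%02d", si)
    per_rank <- vector("list", config$n_peakgroups)
    n_rec <- nrow(universe)
    truly <- c(is_true, rep(FALSE, n_d))
    for (rk in seq_len(config$n_peakgroups)) {
      mu_rows <- if (rk == 1L) truly else rep(FALSE, n_rec)
      feats <- matrix(NA_real_, n_rec, 22L)
      if (any(mu_rows)) {
        feats[mu_rows, ] <- draw_features(sum(mu_rows), mu_true, chol_factor)
      }
      if (any(!mu_rows)) {
        feats[!mu_rows, ] <- draw_features(sum(!mu_rows), mu_null, chol_factor)
      }
      colnames(feats) <- peakgroup_features()
      rec <- data.table(
        sample_id = sample_id,
        precursor_id = universe$precursor_id,
        peakgroup_rank = rk,
        peptide_id = universe$peptide_id,
        protein_group = universe$protein_group,
        decoy = universe$decoy,
        retention_time = pmax(0, universe$base_rt + rnorm(n_rec, 0, 5)),
        truth_label = universe$truth_label,
        species_tag = universe$species_tag
      )
      per_rank[[rk]] <- cbind(rec, as.data.table(feats))
    }
    tab <- rbindlist(per_rank)
    # intensities: quant design on log2 scale, or generic abundances
    log2fc <- if (!is.null(quant)) {
      fc <- quant$log2fc[universe$species_tag]
      fc[is.na(fc)] <- 0
      if (design[[sample_id]] == "B") fc else rep(0, n_rec)
    } else rep(0, n_rec)
    noise_sd <- if (!is.null(quant)) quant$noise_sd else 0.2
    log2_int <- universe$base_log2 + log2fc + rnorm(n_rec, 0, noise_sd)
    intensity <- rep(2^log2_int, config$n_peakgroups)
    if (!is.null(quant) && quant$missing_rate > 0) {
      drop <- runif(length(intensity)) < quant$missing_rate
      intensity[drop] <- NA_real_
    }
    tab[, intensity := intensity]
    samples[[si]] <- as_peakgroup_table(tab)
    sold()
  }

  truth <- universe[, .(
    precursor_id, peptide_id, protein_group, species_tag, truth_label,
    expected_log2fc = if (!is.null(quant)) {
      fc <- quant$log2fc[species_tag]; fc[is.na(fc)] <- 0; fc
    } else 0
  )]
  list(samples = samples, truth = truth[], design = design, config = config)
}

#' Simulate a two-group spike-in experiment
#'
#' Convenience wrapper around [simulate_experiment()] for the two-species
#' spike-in regime: a constant background species with expected log2 fold
#' change 0 and a spiked species with expected log2 fold change 2 (one group
#' receives four times more of it). All targets are true (the spiked
#' peptides really are in the sample), so the quantitative path can be
#' evaluated in isolation. In the noise-free limit (`noise_sd = 0`,
#' `missing_rate = 0`) every spiked-species row reproduces the expected fold
#' change exactly.
#'
#' @param n_replicates Replicates per group.
#' @param n_targets,n_decoys Precursor counts per sample.
#' @param species_mix Named fractions per species.
#' @param log2fc Named expected log2 fold changes per species.
#' @param noise_sd,missing_rate See [quant_design()].
#' @param effect_size,seed See [simulation_config()].
#' @return As [simulate_experiment()].
#' @export
simulate_spikein <- function(n_replicates = 10L, n_targets = 1000L,
                             n_decoys = 1000L,
                             species_mix = c(mouse = 0.8, yeast = 0.2),
                             log2fc = c(mouse = 0, yeast = 2),
                             noise_sd = 0.1, missing_rate = 0,
                             effect_size = 3, seed = 1L) {
  if (!setequal(names(species_mix), names(log2fc))) {
    abort_diascore("config", "species_mix and log2fc must name the same species")
  }
  cfg <- simulation_config(
    n_samples = 2L * n_replicates, n_targets = n_targets,
    true_target_fraction = 1, n_decoys = n_decoys,
    effect_size = effect_size, species_mix = species_mix,
    quant = quant_design(n_replicates = n_replicates, log2fc = log2fc,
                         noise_sd = noise_sd, missing_rate = missing_rate),
    seed = seed
  )
  simulate_experiment(cfg)
}
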