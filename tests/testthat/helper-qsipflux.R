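# Shared fixtures and independent oracles for the test suite.

# A small experiment config: one ecosystem keeps the tables light while
# exercising all three treatments.
small_config <- function(seed = 1, n_taxa = 60, ...) {
  sim_config(n_taxa = n_taxa, ecosystems = "eco1", include_13c = FALSE,
             seed = seed, ...)
}

# Cache the two workhorse simulations across test files.
.fixtures <- new.env(parent = emptyenv())

small_noiseless_sim <- function() {
  if (is.null(.fixtures$noiseless)) {
    .fixtures$noiseless <- simulate_qsip_experiment(noiseless(small_config()))
  }
  .fixtures$noiseless
}

small_noisy_sim <- function() {
  if (is.null(.fixtures$noisy)) {
    .fixtures$noisy <- simulate_qsip_experiment(small_config())
  }
  .fixtures$noisy
}

# High-growth-variance regime: moderate abundance dominance (realistic 16S
# evenness at this richness) with wide growth variation, the setting in
# which carbon use concentrates into fewer taxa than abundance.
evenness_regime_sim <- function() {
  if (is.null(.fixtures$evenness)) {
    .fixtures$evenness <- simulate_qsip_experiment(
      small_config(seed = 7, n_taxa = 120, abund_sdlog = 1.2,
                   growth_sdlog = 1.3))
  }
  .fixtures$evenness
}

flux_table <- function(sim) {
  kin <- run_kinetics(sim)
  comm <- community_cue_table(kin, sim$measurements)
  compute_fluxes(kin, sim$traits,
                 bounds = group_cue_bounds(comm, sim$metadata))
}

run_kinetics <- function(sim, ...) {
  suppressWarnings(suppressMessages(estimate_kinetics(
    sim$fractions, sim$metadata,
    density_window = sim$config$density_range, ...)))
}

# Brute-force occupancy-rule oracle: a literal loop over the retention rule,
# independent of filter_asvs's implementation.
brute_force_filter <- function(occupancy, min_reps, min_fracs) {
  # occupancy: asv x replicate matrix of occupied-fraction counts
  keep <- logical(nrow(occupancy))
  for (i in seq_len(nrow(occupancy))) {
    qualifying <- 0L
    for (r in seq_len(ncol(occupancy))) {
      if (occupancy[i, r] >= min_fracs) qualifying <- qualifying + 1L
    }
    keep[i] <- qualifying >= min_reps
  }
  keep
}

# Build a one-group fraction table + metadata realising a given occupancy
# matrix (counts placed in the first k fractions of each replicate).
occupancy_to_tables <- function(occupancy, n_fractions = 20) {
  n_asv <- nrow(occupancy); n_rep <- ncol(occupancy)
  rows <- list()
  for (r in seq_len(n_rep)) {
    for (i in seq_len(n_asv)) {
      k <- occupancy[i, r]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0("s", r),
          fraction_id = sprintf("F%02d", seq_len(k)),
          density_g_cm3 = 1.64 + 0.005 * seq_len(k),
          copies_per_g = 1e6,
          asv_id = sprintf("A%03d", i),
          count = 5)
      }
    }
  }
  fractions <- do.call(rbind, rows)
  metadata <- data.frame(sample_id = paste0("s", seq_len(n_rep)),
                         ecosystem = "e1", treatment = "t1",
                         replicate = paste0("r", seq_len(n_rep)),
                         isotope = "18O", t_days = 7)
  list(fractions = fractions, metadata = metadata)
}
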