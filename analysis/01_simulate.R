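#!/usr/bin/env Rscript
# Stage 1: forward-simulate a qSIP incubation experiment.
#
# Two ecosystems x three nutrient treatments (none / glucose / glucose+N)
# x three replicates, each with paired 18O-water and natural-abundance
# incubations, plus parallel 13C-glucose pairs in the amended treatments.
# Ground truth (per-taxon growth, CUE, enrichment) is exported alongside
# the observable tables so downstream stages can be validated.

library(qsipflux)

# abund_sdlog 1.2 gives Pielou evenness of abundance around 0.7-0.85 at this
# richness, matching what 16S surveys of soil typically report
cfg <- sim_config(ecosystems = c("eco1", "eco2"), include_13c = TRUE,
                  abund_sdlog = 1.2, seed = 1)
sim <- simulate_qsip_experiment(cfg)
paths <- write_simulation(sim, "results/data")

cat("samples simulated:        ", nrow(sim$metadata), "\n")
cat("  18O / unlabeled pairs:  ", sum(sim$metadata$isotope == "18O"), "\n")
cat("  13C / unlabeled pairs:  ", sum(sim$metadata$isotope == "13C"), "\n")
cat("fraction-table rows:      ", nrow(sim$fractions), "\n")
cat("taxa in community pool:   ", cfg$n_taxa, "\n")
cat("true growth, median (ctl):",
    signif(median(sim$community$growth$g[
      sim$community$growth$treatment == "control"]), 3), "per day\n")
cat("files written under results/data/:",
    paste(basename(paths), collapse = ", "), "\n")
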