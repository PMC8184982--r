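#!/usr/bin/env Rscript
# Stage 4: rank the candidate growth-to-CUE functional forms.
#
# Five forms (linear increase/decrease, exponential decline, unimodal with
# vertex at 0.5 and at 0.05 day^-1), each evaluated constrained by the
# observed community CUE range of its replicate group and unconstrained
# within fixed global bounds. Scored by AIC of z-transformed regressions:
# summed per-taxon respiration against measured respiration (doubled) plus
# abundance-weighted CUE against community CUE.

library(qsipflux)

kin <- utils::read.csv("results/kinetics.csv")
taxonomy <- read_taxonomy_tsv("results/data/taxonomy.tsv")
reference <- read_traits_tsv("results/data/traits.tsv")
measurements <- utils::read.csv("results/data/measurements.csv")
metadata <- read_metadata_csv("results/data/metadata.csv")

traits <- assign_genome_traits(taxonomy, reference)
sel <- select_cue_model(kin, traits, measurements, metadata)

report <- sel[, c("form", "constrained", "delta_aic_co2", "delta_aic_cue",
                  "delta_aic_combined")]
report[, 3:5] <- signif(report[, 3:5], 4)
print(report, row.names = FALSE)
cat("selected form:", sel$form[1],
    if (sel$constrained[1]) "(constrained)" else "(unconstrained)", "\n")

utils::write.csv(sel, "results/cue_model_selection.csv", row.names = FALSE)
cat("written: results/cue_model_selection.csv\n")
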