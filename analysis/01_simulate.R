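#!/usr/bin/env Rscript
# Generate one synthetic realisation of the study's four datasets under the
# default conditions and write them as the CSV schemas the later stages read.

library(shelfsense)

seed <- 1
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- synthetic_config()

qim <- gen_qim(cfg, seed = seed)
write_table(qim, file.path(out_dir, "qim_scores.csv"), "qim_scores")

tet <- gen_tetrad(cfg$tetrad$n, cfg$tetrad$dprime, seed = seed)
utils::write.csv(tet$responses, file.path(out_dir, "tetrad_responses.csv"),
                 row.names = FALSE, quote = FALSE)

growth <- gen_growth(cfg$growth$params, cfg$growth$days, cfg$growth$sd,
                     cfg$growth$replicates, seed = seed)
write_table(growth, file.path(out_dir, "growth_counts.csv"), "growth_counts")

da <- gen_da(sd_assessor = cfg$da$sd_assessor,
             sd_replicate = cfg$da$sd_replicate,
             n_assessors = cfg$da$n_assessors,
             replicates = cfg$da$replicates, seed = seed)
write_table(da, file.path(out_dir, "da_scores.csv"), "da_scores")

cat(sprintf(
  "seed %d: wrote %d QIM evaluations, %d tetrad responses (%d correct),\n",
  seed, nrow(qim), tet$n_assessors, tet$n_correct))
cat(sprintf("  %d plate counts and %d DA intensity records under %s\n",
            nrow(growth), nrow(da), out_dir))
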