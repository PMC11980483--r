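#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-genotype photoperiod experiment.
#
# Emulates the study design: genotype A (flowers under long days) sampled at
# 13/15/19 DAS, genotype B (flowers under short days) at 14/21/24 DAS, both
# under LD and SD, twice daily, three biological replicates — 72 libraries.
# 2000 genes with planted classes: 20 contrast, 50 concordant, 50 diurnal,
# 100 low-expression, the rest null.

suppressMessages(library(photorank))

out_dir <- "results/analysis/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)   # package defaults = study conditions
sim <- simulate_experiment(cfg)

write_counts_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
write_design_tsv(sim$design, file.path(out_dir, "design.tsv"))
write_truth_tsv(sim$truth, file.path(out_dir, "truth.tsv"))

message(sprintf("simulated %d genes x %d libraries", nrow(sim$counts),
                ncol(sim$counts)))
message("planted classes: ",
        paste(names(table(sim$truth$class)), table(sim$truth$class),
              sep = "=", collapse = ", "))
message("wrote counts/design/truth TSVs under ", out_dir)
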