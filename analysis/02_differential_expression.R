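#!/usr/bin/env Rscript
# Stage 2: LD-vs-SD differential expression at every inductive sampling
# point. The floral-induction window is each genotype's two later sampling
# days; morning and afternoon series are tested separately, giving
# 2 genotypes x 2 days x 2 times-of-day = 8 comparisons.

suppressMessages(library(photorank))

data_dir <- "results/analysis/data"
out_dir <- "results/analysis/de"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts_tsv(file.path(data_dir, "counts.tsv"))
design <- read_design_tsv(file.path(data_dir, "design.tsv"))
validate_experiment(counts, design)

windows <- lapply(split(design$day, design$genotype), induction_days)
for (tod in c("morning", "afternoon")) {
  for (geno in names(windows)) {
    for (day in windows[[geno]]) {
      tab <- de_test(counts, design, geno, day, tod)
      path <- file.path(out_dir, sprintf("de_%s_%s_d%02d.tsv", tod, geno, day))
      write_de_tsv(tab, path)
      message(sprintf("%-9s genotype %s day %2d: %4d DEGs at FDR 0.05",
                      tod, geno, day, sum(tab$is_deg)))
    }
  }
}
message("wrote 8 differential tables under ", out_dir)
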