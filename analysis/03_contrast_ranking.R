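#!/usr/bin/env Rscript
# Stage 3: rank-sum contrast scoring. Within each diurnal dataset, DEGs are
# ranked by logFC (LD-first in genotype A, SD-first in genotype B), the four
# ranks are summed, and the lowest-scoring sign-consistent genes become that
# dataset's candidates. Genes with low or fluctuating expression are removed
# first.

suppressMessages(library(photorank))

data_dir <- "results/analysis/data"
de_dir <- "results/analysis/de"
out_dir <- "results/analysis/contrast"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts_tsv(file.path(data_dir, "counts.tsv"))
design <- read_design_tsv(file.path(data_dir, "design.tsv"))
windows <- lapply(split(design$day, design$genotype), induction_days)
top_k <- 20

for (tod in c("morning", "afternoon")) {
  window_design <- design[
    design$time_of_day == tod &
      ((design$genotype == "A" & design$day %in% windows$A) |
       (design$genotype == "B" & design$day %in% windows$B)), ]
  eligible <- filter_genes(counts, window_design)

  tabs <- list()
  for (geno in names(windows)) for (day in windows[[geno]]) {
    path <- file.path(de_dir, sprintf("de_%s_%s_d%02d.tsv", tod, geno, day))
    tabs[[length(tabs) + 1L]] <- read_de_tsv(path, genotype = geno,
                                             day = day, time_of_day = tod)
  }
  sc <- contrast_score(tabs, eligible = eligible)
  sel <- select_candidates(sc, top_k = top_k)
  write.table(sc, file.path(out_dir, sprintf("scores_%s.tsv", tod)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sel, file.path(out_dir, sprintf("candidates_%s.tsv", tod)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%-9s: %d/%d genes eligible, %d scored in all 4 comparisons, %d selected",
    tod, length(eligible), nrow(counts), nrow(sc), nrow(sel)))
}
message("wrote score and candidate tables under ", out_dir)
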