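#!/usr/bin/env Rscript
# Stage 4: combine the independently derived morning and afternoon candidate
# sets (union with inclusion-exclusion accounting) and score the final list
# against the planted truth.

suppressMessages(library(photorank))

data_dir <- "results/analysis/data"
ct_dir <- "results/analysis/contrast"
out_dir <- "results/analysis/report"

read_sel <- function(tod)
  read.delim(file.path(ct_dir, sprintf("candidates_%s.tsv", tod)),
             stringsAsFactors = FALSE)
read_sc <- function(tod)
  read.delim(file.path(ct_dir, sprintf("scores_%s.tsv", tod)),
             stringsAsFactors = FALSE)

candidates <- combine_diurnal(read_sel("morning"), read_sel("afternoon"))
print(candidates)

truth <- read_truth_tsv(file.path(data_dir, "truth.tsv"))
rep_out <- write_candidate_report(candidates, read_sc("morning"),
                                  read_sc("afternoon"), truth = truth,
                                  out_dir = out_dir)
m <- rep_out$summary$metrics
message(sprintf("recovery vs planted truth: precision %.2f, recall %.2f, F1 %.2f",
                m$precision, m$recall, m$f1))
message("wrote ", rep_out$paths["tsv"], " and ", rep_out$paths["json"])
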