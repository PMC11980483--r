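# Small fixtures built in code.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60L, n_contrast = 5L, n_concordant = 5L, n_diurnal = 5L,
         n_low = 5L, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

null_config <- function(n_genes = 2000L, seed = 1L, ...) {
  sim_config(n_genes = n_genes, n_contrast = 0L, n_concordant = 0L,
             n_diurnal = 0L, n_low = 0L, seed = seed, ...)
}

# A random differential table with attributes, for ranking tests.
random_de_table <- function(n, genotype, day, tod = "morning",
                            deg_prob = 0.6, tie_frac = 0.3) {
  ids <- sprintf("g%04d", seq_len(n))
  lfc <- stats::rnorm(n, 0, 2)
  rough <- sample.int(n, size = floor(n * tie_frac))
  lfc[rough] <- round(lfc[rough], 1)  # force some exact ties
  tab <- data.frame(
    gene_id = sample(ids),            # scrambled row order on purpose
    log_fc = lfc,
    base_mean = stats::runif(n, 1, 100),
    p_raw = stats::runif(n),
    fdr = stats::runif(n),
    is_deg = stats::runif(n) < deg_prob,
    stringsAsFactors = FALSE
  )
  attr(tab, "genotype") <- genotype
  attr(tab, "day") <- day
  attr(tab, "time_of_day") <- tod
  tab
}

random_table_quartet <- function(n, ...) {
  list(random_de_table(n, "A", 2, ...),
       random_de_table(n, "A", 3, ...),
       random_de_table(n, "B", 3, ...),
       random_de_table(n, "B", 4, ...))
}

# Counts where most genes are flat across samples (anchoring size factors at
# 1) and selected genes carry a planted LD/SD pattern.
flat_experiment <- function(n_genes = 30, replicates = 3) {
  cfg <- sim_config(n_genes = n_genes, n_contrast = 0, n_concordant = 0,
                    n_diurnal = 0, n_low = 0, replicates = replicates,
                    days_genotype_A = c(1, 2), days_genotype_B = c(1, 2),
                    seed = 1)
  design <- design_table(cfg)
  counts <- matrix(50L, nrow = n_genes, ncol = nrow(design),
                   dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                                   design$sample_id))
  list(counts = counts, design = design)
}
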