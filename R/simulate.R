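#' Simulation configuration
#'
#' Describes a synthetic two-genotype photoperiod experiment: an LD-flowering
#' genotype "A" and an SD-flowering genotype "B", each grown under long-day
#' (LD) and short-day (SD) photoperiods, sampled on three days after sowing
#' (DAS), twice daily (morning/afternoon), with replicated libraries.
#'
#' Gene classes planted in the simulated transcriptome:
#' \describe{
#'   \item{contrast}{opposite photoperiod response between genotypes: up under
#'     LD in genotype A and up under SD in genotype B, by
#'     `interaction_effect` log2 units, on the two later (inductive) sampling
#'     days of each genotype only.}
#'   \item{concordant}{photoperiod-responsive with the same sign in both
#'     genotypes (half LD-up, half SD-up), on all days.}
#'   \item{diurnal}{time-of-day oscillators (half morning-up, half
#'     afternoon-up) with amplitude `diurnal_amplitude`, photoperiod-blind.}
#'   \item{low}{expressed below the default low-expression filter
#'     (log2 baseline drawn from `low_log2_mean_range`).}
#'   \item{null}{baseline expression only.}
#' }
#'
#' @param n_genes total number of genes.
#' @param n_contrast,n_concordant,n_diurnal,n_low planted class sizes; the
#'   remainder of the transcriptome is null.
#' @param replicates biological replicates per condition (>= 2).
#' @param days_genotype_A,days_genotype_B sampling days (DAS) per genotype.
#'   The two later days of each genotype form the floral-induction window that
#'   carries the contrast effect.
#' @param baseline_log2_mean_range interval the log2 baseline mean of
#'   expressed genes is drawn from (uniform).
#' @param low_log2_mean_range same, for the low-expression class.
#' @param interaction_effect log2 fold change planted for the contrast and
#'   concordant classes.
#' @param diurnal_amplitude log2 amplitude of the diurnal class.
#' @param day_drift log2 drift in mean expression per day after the
#'   genotype's first sampling day, applied to every gene, so sampling days
#'   are not exact replicates of each other.
#' @param dispersion negative binomial dispersion alpha in
#'   var = mu + alpha * mu^2.
#' @param libsize_sigma standard deviation of log-normal per-sample size
#'   factors (re-centred so their median is exactly 1).
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_contrast = 20L,
                       n_concordant = 50L,
                       n_diurnal = 50L,
                       n_low = 100L,
                       replicates = 3L,
                       days_genotype_A = c(13L, 15L, 19L),
                       days_genotype_B = c(14L, 21L, 24L),
                       baseline_log2_mean_range = c(5, 12),
                       low_log2_mean_range = c(-1, 1.5),
                       interaction_effect = 2,
                       diurnal_amplitude = 1.5,
                       day_drift = 0.1,
                       dispersion = 0.05,
                       libsize_sigma = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_contrast = as.integer(n_contrast),
    n_concordant = as.integer(n_concordant),
    n_diurnal = as.integer(n_diurnal),
    n_low = as.integer(n_low),
    replicates = as.integer(replicates),
    days_genotype_A = as.integer(days_genotype_A),
    days_genotype_B = as.integer(days_genotype_B),
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    low_log2_mean_range = as.numeric(low_log2_mean_range),
    interaction_effect = as.numeric(interaction_effect),
    diurnal_amplitude = as.numeric(diurnal_amplitude),
    day_drift = as.numeric(day_drift),
    dispersion = as.numeric(dispersion),
    libsize_sigma = as.numeric(libsize_sigma),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L)
    stop("invalid sim_config: n_genes must be a positive integer", call. = FALSE)
  planted <- cfg$n_contrast + cfg$n_concordant + cfg$n_diurnal + cfg$n_low
  if (any(c(cfg$n_contrast, cfg$n_concordant, cfg$n_diurnal, cfg$n_low) < 0L))
    stop("invalid sim_config: planted class sizes must be non-negative",
         call. = FALSE)
  if (planted > cfg$n_genes)
    stop("invalid sim_config: n_contrast + n_concordant + n_diurnal + n_low ",
         "exceeds n_genes", call. = FALSE)
  if (cfg$replicates < 2L)
    stop("invalid sim_config: replicates must be >= 2", call. = FALSE)
  if (is.na(cfg$dispersion) || cfg$dispersion < 0)
    stop("invalid sim_config: dispersion must be >= 0", call. = FALSE)
  if (!is.finite(cfg$interaction_effect))
    stop("invalid sim_config: interaction_effect must be finite", call. = FALSE)
  if (length(cfg$days_genotype_A) < 2L || length(cfg$days_genotype_B) < 2L)
    stop("invalid sim_config: each genotype needs at least two sampling days",
         call. = FALSE)
  if (anyDuplicated(cfg$days_genotype_A) || anyDuplicated(cfg$days_genotype_B))
    stop("invalid sim_config: sampling days must be distinct", call. = FALSE)
  if (length(cfg$baseline_log2_mean_range) != 2L ||
      diff(cfg$baseline_log2_mean_range) < 0)
    stop("invalid sim_config: baseline_log2_mean_range must be an interval",
         call. = FALSE)
  if (cfg$libsize_sigma < 0)
    stop("invalid sim_config: libsize_sigma must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Build the sample design table for a configuration
#'
#' One row per sequencing library: genotype x photoperiod x day x time-of-day
#' x replicate. Sample identifiers encode the condition.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame with columns `sample_id`, `genotype`, `photoperiod`,
#'   `day`, `time_of_day`, `replicate`.
#' @export
design_table <- function(config) {
  validate_sim_config(config)
  blocks <- lapply(c("A", "B"), function(geno) {
    days <- if (geno == "A") config$days_genotype_A else config$days_genotype_B
    expand.grid(
      replicate = seq_len(config$replicates),
      time_of_day = c("morning", "afternoon"),
      photoperiod = c("LD", "SD"),
      day = sort(days),
      genotype = geno,
      stringsAsFactors = FALSE,
      KEEP.OUT.ATTRS = FALSE
    )
  })
  d <- do.call(rbind, blocks)
  d <- d[, c("genotype", "photoperiod", "day", "time_of_day", "replicate")]
  d$sample_id <- sprintf("%s_%s_d%02d_%s_r%d", d$genotype, d$photoperiod,
                         d$day, d$time_of_day, d$replicate)
  rownames(d) <- NULL
  d[, c("sample_id", "genotype", "photoperiod", "day", "time_of_day",
        "replicate")]
}

#' Days forming the floral-induction window of a genotype
#'
#' The two later sampling days of the genotype; the first day is treated as
#' pre-induction baseline.
#'
#' @param days integer vector of sampling days.
#' @return the two largest days, sorted.
#' @export
induction_days <- function(days) {
  days <- sort(unique(as.integer(days)))
  if (length(days) < 2L)
    stop("need at least two sampling days to define an induction window",
         call. = FALSE)
  utils::tail(days, 2L)
}

#' Simulate a two-genotype photoperiod RNA-seq experiment
#'
#' Draws a gene-by-sample count matrix from a negative binomial model
#' (var = mu + alpha * mu^2) with log-normal library size factors and the
#' planted gene classes described in [sim_config()]. Expected means follow
#' log2 q_gj = baseline_g + day drift + class effects; counts are
#' NB(mu = s_j * q_gj, dispersion alpha).
#'
#' @param config a [sim_config()] object.
#' @return a list with components:
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with gene ids as row
#'       names and sample ids as column names; the expected mean matrix
#'       `s_j * q_gj` is attached as attribute `"mu"` and the size factors as
#'       attribute `"size_factors"`.}
#'     \item{design}{the [design_table()] of the configuration.}
#'     \item{truth}{data.frame `gene_id`, `class`, `direction` (contrast genes
#'       are `"LD_up_A_SD_up_B"`; other classes carry their own sub-direction
#'       or `NA`).}
#'   }
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 50, n_contrast = 5,
#'                                       n_concordant = 5, n_diurnal = 5,
#'                                       n_low = 5, seed = 42))
#' dim(sim$counts)
#' table(sim$truth$class)
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  design <- design_table(config)
  n_samp <- nrow(design)
  g <- config$n_genes

  gene_id <- sprintf("gene%05d", seq_len(g))
  class <- rep("null", g)
  idx <- 0L
  take <- function(n) {
    out <- seq_len(n) + idx
    idx <<- idx + n
    out
  }
  i_contrast <- take(config$n_contrast)
  i_concord <- take(config$n_concordant)
  i_diurnal <- take(config$n_diurnal)
  i_low <- take(config$n_low)
  class[i_contrast] <- "contrast"
  class[i_concord] <- "concordant"
  class[i_diurnal] <- "diurnal"
  class[i_low] <- "low"

  direction <- rep(NA_character_, g)
  direction[i_contrast] <- "LD_up_A_SD_up_B"
  # concordant: alternate LD-up / SD-up; diurnal: morning-up / afternoon-up
  concord_ld_up <- rep(c(TRUE, FALSE), length.out = length(i_concord))
  direction[i_concord] <- ifelse(concord_ld_up, "LD_up_both", "SD_up_both")
  diurnal_am_up <- rep(c(TRUE, FALSE), length.out = length(i_diurnal))
  direction[i_diurnal] <- ifelse(diurnal_am_up, "morning_up", "afternoon_up")

  set.seed(config$seed)
  baseline <- stats::runif(g, config$baseline_log2_mean_range[1],
                           config$baseline_log2_mean_range[2])
  if (length(i_low))
    baseline[i_low] <- stats::runif(length(i_low),
                                    config$low_log2_mean_range[1],
                                    config$low_log2_mean_range[2])

  sf <- exp(stats::rnorm(n_samp, 0, config$libsize_sigma))
  sf <- sf / stats::median(sf)

  ind_A <- induction_days(config$days_genotype_A)
  ind_B <- induction_days(config$days_genotype_B)
  day0 <- ifelse(design$genotype == "A", min(config$days_genotype_A),
                 min(config$days_genotype_B))
  drift <- config$day_drift * (design$day - day0)

  # log2 expected means per gene x sample
  log2q <- matrix(baseline, nrow = g, ncol = n_samp) +
    matrix(drift, nrow = g, ncol = n_samp, byrow = TRUE)

  in_window <- (design$genotype == "A" & design$day %in% ind_A) |
    (design$genotype == "B" & design$day %in% ind_B)
  contrast_on <- in_window &
    ((design$genotype == "A" & design$photoperiod == "LD") |
     (design$genotype == "B" & design$photoperiod == "SD"))
  if (length(i_contrast))
    log2q[i_contrast, contrast_on] <-
      log2q[i_contrast, contrast_on] + config$interaction_effect

  if (length(i_concord)) {
    is_ld <- design$photoperiod == "LD"
    log2q[i_concord[concord_ld_up], is_ld] <-
      log2q[i_concord[concord_ld_up], is_ld] + config$interaction_effect
    log2q[i_concord[!concord_ld_up], !is_ld] <-
      log2q[i_concord[!concord_ld_up], !is_ld] + config$interaction_effect
  }

  if (length(i_diurnal)) {
    is_am <- design$time_of_day == "morning"
    log2q[i_diurnal[diurnal_am_up], is_am] <-
      log2q[i_diurnal[diurnal_am_up], is_am] + config$diurnal_amplitude
    log2q[i_diurnal[!diurnal_am_up], !is_am] <-
      log2q[i_diurnal[!diurnal_am_up], !is_am] + config$diurnal_amplitude
  }

  mu <- 2^log2q * matrix(sf, nrow = g, ncol = n_samp, byrow = TRUE)
  counts <- if (config$dispersion > 0) {
    stats::rnbinom(g * n_samp, mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(g * n_samp, lambda = mu)
  }
  counts <- matrix(as.integer(counts), nrow = g, ncol = n_samp,
                   dimnames = list(gene_id, design$sample_id))
  dimnames(mu) <- dimnames(counts)
  attr(counts, "mu") <- mu
  attr(counts, "size_factors") <- stats::setNames(sf, design$sample_id)

  list(
    counts = counts,
    design = design,
    truth = data.frame(gene_id = gene_id, class = class,
                       direction = direction, stringsAsFactors = FALSE)
  )
}
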