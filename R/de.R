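#' Median-of-ratios size factors
#'
#' Library-size normalization factors computed against a geometric-mean
#' pseudo-reference built from genes with no zero count: for sample j,
#' the factor is the median over reference genes of count_gj / geomean_g.
#' Because each ratio compares a sample to the gene's own geometric mean
#' across samples, the factors capture relative library depth only:
#' rescaling the whole matrix by a constant leaves every factor unchanged,
#' so normalized counts stay on the scale of the raw counts.
#'
#' @param counts nonnegative numeric matrix, genes x samples.
#' @return positive numeric vector, one factor per sample (named by column).
#' @examples
#' m <- matrix(rpois(60, 50), nrow = 15)
#' size_factors(m)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene with all-positive counts; filter the matrix to genes ",
         "detected in every sample before computing size factors",
         call. = FALSE)
  ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  sf <- apply(counts[all_pos, , drop = FALSE], 2,
              function(col) stats::median(col / ref))
  if (any(sf <= 0))
    stop("non-positive size factor; matrix too sparse to normalize",
         call. = FALSE)
  sf
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples matrix.
#' @param sf optional size factors; computed with [size_factors()] if missing.
#' @return matrix of normalized counts (counts divided column-wise by factors).
#' @export
normalize_counts <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, "/")
}

#' Gene-wise negative binomial dispersion by method of moments
#'
#' For each replicate group k with per-gene sample mean m_k and sample
#' variance s2_k, the moment term is (s2_k - m_k) / m_k^2 (the plug-in
#' solution of var = mu + alpha * mu^2). The gene's dispersion is the mean of
#' the terms over groups, floored at 1e-8. Supplying several replicate groups
#' (e.g. every condition of an experiment) pools information and stabilizes
#' the estimate; with a single pair of groups of equal means this reduces to
#' the classical pooled two-group moment estimator.
#'
#' @param groups a list of numeric matrices (genes x replicates, normalized
#'   counts), all with the same genes in the same order; each group needs
#'   >= 2 replicates.
#' @param floor lower bound for the estimate.
#' @return numeric vector of per-gene dispersions, with attribute `"df"` =
#'   sum over groups of (replicates - 1), the degrees of freedom behind the
#'   variance estimates.
#' @examples
#' g1 <- matrix(c(90, 100, 110), nrow = 1)
#' g2 <- matrix(c(95, 100, 105), nrow = 1)
#' estimate_dispersion(list(g1, g2))  # variance < mean: floored
#' @export
estimate_dispersion <- function(groups, floor = 1e-8) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("groups must be a non-empty list of matrices", call. = FALSE)
  groups <- lapply(groups, as.matrix)
  n_genes <- nrow(groups[[1]])
  for (y in groups) {
    if (nrow(y) != n_genes)
      stop("all groups must cover the same genes", call. = FALSE)
    if (ncol(y) < 2L)
      stop("each replicate group needs at least 2 replicates to estimate ",
           "dispersion", call. = FALSE)
  }
  terms <- vapply(groups, function(y) {
    n <- ncol(y)
    m <- rowMeans(y)
    v <- rowSums((y - m)^2) / (n - 1)
    out <- (v - m) / m^2
    out[m == 0] <- NA_real_
    out
  }, numeric(n_genes))
  terms <- matrix(terms, nrow = n_genes)
  alpha <- rowMeans(terms, na.rm = TRUE)
  alpha[is.nan(alpha)] <- floor   # all groups zero-mean
  alpha <- pmax(floor, alpha)
  attr(alpha, "df") <- sum(vapply(groups, ncol, 1L) - 1L)
  alpha
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, via
#' [stats::p.adjust()]. Inputs outside \[0, 1\] are rejected.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, elementwise >= the input, in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p))
    stop("p-values must be numeric", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

subset_group <- function(counts, design, genotype, photoperiod, day,
                         time_of_day) {
  keep <- design$genotype == genotype & design$photoperiod == photoperiod &
    design$day == day & design$time_of_day == time_of_day
  design$sample_id[keep]
}

#' Per-time-point LD-vs-SD differential expression
#'
#' Tests every gene for differential expression between the long-day and
#' short-day groups of one (genotype, day, time-of-day) sampling point.
#' Counts are normalized by median-of-ratios size factors computed on the
#' full supplied matrix; gene-wise dispersion is estimated by method of
#' moments pooled over every replicate group in the design (see
#' [estimate_dispersion()]). The log2 fold change is
#' log2((m_LD + c0) / (m_SD + c0)) with pseudocount c0, its standard error
#' comes from the delta method on the negative binomial group means,
#' SE^2 = (1/ln 2)^2 \* \[(1/n_LD)(1/(m_LD + c0) + alpha) +
#' (1/n_SD)(1/(m_SD + c0) + alpha)\],
#' and the Wald statistic logFC / SE is referred to a Student t distribution
#' whose degrees of freedom equal those behind the dispersion estimate.
#' Genes with base mean below `min_base_mean` are not tested (p = 1).
#'
#' @param counts genes x samples count matrix (all samples of the
#'   experiment; used for normalization and dispersion pooling).
#' @param design companion design table with columns `sample_id`, `genotype`,
#'   `photoperiod`, `day`, `time_of_day`, `replicate`.
#' @param genotype,day,time_of_day the sampling point to test.
#' @param fdr_threshold FDR cutoff defining `is_deg` (default 0.05).
#' @param pseudocount c0 added to group means in the fold change (default
#'   0.5), keeping logFC finite and sign-faithful at zero means.
#' @param min_base_mean genes with mean normalized count (over the two
#'   groups) below this floor are assigned p = 1 rather than tested.
#' @return a data.frame (one row per gene) with columns `gene_id`, `log_fc`,
#'   `base_mean`, `p_raw`, `fdr`, `is_deg`, carrying the comparison key as
#'   attributes `genotype`, `day`, `time_of_day`.
#' @export
de_test <- function(counts, design, genotype, day, time_of_day,
                    fdr_threshold = 0.05, pseudocount = 0.5,
                    min_base_mean = 1) {
  counts <- as.matrix(counts)
  validate_experiment(counts, design)
  ld <- subset_group(counts, design, genotype, "LD", day, time_of_day)
  sd_ <- subset_group(counts, design, genotype, "SD", day, time_of_day)
  if (length(ld) < 2L)
    stop(sprintf("missing or under-replicated group: (LD, %s, day %s, %s)",
                 genotype, day, time_of_day), call. = FALSE)
  if (length(sd_) < 2L)
    stop(sprintf("missing or under-replicated group: (SD, %s, day %s, %s)",
                 genotype, day, time_of_day), call. = FALSE)

  norm <- normalize_counts(counts)
  key <- interaction(design$genotype, design$photoperiod, design$day,
                     design$time_of_day, drop = TRUE)
  groups <- split(design$sample_id, key)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  alpha <- estimate_dispersion(
    lapply(groups, function(s) norm[, s, drop = FALSE]))
  df <- attr(alpha, "df")
  alpha <- as.numeric(alpha)

  m_ld <- rowMeans(norm[, ld, drop = FALSE])
  m_sd <- rowMeans(norm[, sd_, drop = FALSE])
  base_mean <- rowMeans(norm[, c(ld, sd_), drop = FALSE])

  log_fc <- log2((m_ld + pseudocount) / (m_sd + pseudocount))
  se2 <- (1 / log(2))^2 *
    ((1 / length(ld)) * (1 / (m_ld + pseudocount) + alpha) +
     (1 / length(sd_)) * (1 / (m_sd + pseudocount) + alpha))
  z <- log_fc / sqrt(se2)
  p <- 2 * stats::pt(-abs(z), df = df)
  p[base_mean < min_base_mean] <- 1
  fdr <- bh_adjust(p)

  out <- data.frame(
    gene_id = rownames(counts),
    log_fc = unname(log_fc),
    base_mean = unname(base_mean),
    p_raw = unname(p),
    fdr = unname(fdr),
    is_deg = unname(fdr <= fdr_threshold),
    stringsAsFactors = FALSE
  )
  attr(out, "genotype") <- genotype
  attr(out, "day") <- day
  attr(out, "time_of_day") <- time_of_day
  out
}
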