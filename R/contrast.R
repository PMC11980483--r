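#' Expression-level and replicate-variability gene filter
#'
#' Reproduces the screening rule that genes with too low or too fluctuating
#' expression are not considered candidates: a gene is eligible when its mean
#' normalized count over the supplied samples is at least `min_mean` AND its
#' within-condition replicate coefficient of variation (sd / mean) is at most
#' `max_cv` in every condition (genotype x photoperiod x day x time-of-day)
#' present in `design`. Pass a design restricted to the analyzed time window
#' to filter on that window only.
#'
#' @param counts genes x samples count matrix (may contain more samples than
#'   `design`; normalization uses all of them).
#' @param design design rows defining the conditions to screen.
#' @param min_mean minimum mean normalized count (default 5).
#' @param max_cv maximum within-condition CV (default 1). Conditions with a
#'   zero mean fail the CV criterion.
#' @return character vector of eligible gene ids (possibly empty, with a
#'   warning).
#' @export
filter_genes <- function(counts, design, min_mean = 5, max_cv = 1) {
  counts <- as.matrix(counts)
  if (!all(design$sample_id %in% colnames(counts)))
    stop("design contains sample ids absent from the count matrix",
         call. = FALSE)
  norm <- normalize_counts(counts)[, design$sample_id, drop = FALSE]
  keep_mean <- rowMeans(norm) >= min_mean

  key <- interaction(design$genotype, design$photoperiod, design$day,
                     design$time_of_day, drop = TRUE)
  keep_cv <- rep(TRUE, nrow(norm))
  for (s in split(design$sample_id, key)) {
    if (length(s) < 2L) next
    y <- norm[, s, drop = FALSE]
    m <- rowMeans(y)
    sd_ <- sqrt(rowSums((y - m)^2) / (length(s) - 1))
    cv <- ifelse(m > 0, sd_ / m, Inf)
    keep_cv <- keep_cv & cv <= max_cv
  }
  eligible <- rownames(norm)[keep_mean & keep_cv]
  if (length(eligible) == 0L)
    warning("no gene passed the expression filters; candidate set will be empty",
            call. = FALSE)
  eligible
}

#' Direction-aware ranking of DEGs by log fold change
#'
#' Rank 1 goes to the most contrast-consistent gene: with `LD_first`, genes
#' are ordered by descending logFC (most LD-up first); with `SD_first`, by
#' ascending logFC (most SD-up first). Ties are broken deterministically by
#' lexicographic gene id.
#'
#' @param table a differential table (as from [de_test()]) already restricted
#'   to the genes to rank (typically eligible DEGs).
#' @param direction `"LD_first"` or `"SD_first"`.
#' @return named integer vector mapping gene id to rank (empty for an empty
#'   table).
#' @export
rank_by_logfc <- function(table, direction = c("LD_first", "SD_first")) {
  direction <- match.arg(direction)
  if (nrow(table) == 0L) return(stats::setNames(integer(0), character(0)))
  key <- if (direction == "LD_first") -table$log_fc else table$log_fc
  ord <- order(key, table$gene_id)
  stats::setNames(seq_along(ord), table$gene_id[ord])
}

#' Cross-genotype rank-sum contrast score
#'
#' The core screening statistic: each gene is ranked by logFC within each of
#' the four inductive comparisons — genotype A at its two later sampling
#' points ranked LD-first, genotype B at its two later points ranked SD-first
#' — and the four ranks are summed. Genes with the lowest sums respond to
#' photoperiod most contrastingly: up under LD in the LD-flowering genotype
#' and up under SD in the SD-flowering one.
#'
#' Under the default `"intersection"` universe policy only genes that are
#' (eligible) DEGs in all four comparisons are ranked, and ranks are
#' permutations of 1..N over that shared universe. Under `"penalty"`, each
#' comparison ranks its own DEG set (size N_c) and a gene missing from it
#' receives rank N_c + 1.
#'
#' @param tables list of four differential tables (from [de_test()] or
#'   [read_de_tsv()]): two for genotype A, two for genotype B, all from the
#'   same time-of-day dataset.
#' @param eligible optional character vector of gene ids that passed
#'   [filter_genes()]; if supplied, ranking is restricted to it.
#' @param universe_policy `"intersection"` (default) or `"penalty"`.
#' @return a data.frame sorted ascending by `score` (ties by gene id) with
#'   columns `gene_id`, `rank_1`..`rank_4`, `score`, `lfc_1`..`lfc_4`,
#'   `deg_in_all`; comparison keys are attached as attribute `"comparisons"`.
#' @export
contrast_score <- function(tables, eligible = NULL,
                           universe_policy = c("intersection", "penalty")) {
  universe_policy <- match.arg(universe_policy)
  if (!is.list(tables) || length(tables) != 4L)
    stop("contrast_score needs exactly four differential tables", call. = FALSE)
  tods <- unique(unlist(lapply(tables, attr, "time_of_day")))
  if (length(tods) > 1L)
    stop("all four tables must come from the same time-of-day dataset (found: ",
         paste(tods, collapse = ", "), ")", call. = FALSE)
  genos <- vapply(tables, function(t) as.character(attr(t, "genotype")), "")
  if (any(is.na(genos)) || !setequal(unique(genos), c("A", "B")) ||
      sum(genos == "A") != 2L)
    stop("expected two genotype-A and two genotype-B tables", call. = FALSE)
  # order as A, A, B, B (within genotype, by day if available)
  days <- vapply(tables, function(t) {
    d <- attr(t, "day")
    if (is.null(d)) NA_real_ else as.numeric(d)
  }, 1)
  tables <- tables[order(genos, days)]
  genos <- genos[order(genos, days)]

  degsets <- lapply(tables, function(t) {
    ids <- t$gene_id[t$is_deg]
    if (!is.null(eligible)) ids <- intersect(ids, eligible)
    ids
  })

  if (universe_policy == "intersection") {
    universe <- Reduce(intersect, degsets)
    ranked <- lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      rank_by_logfc(t[t$gene_id %in% universe, , drop = FALSE],
                    if (genos[i] == "A") "LD_first" else "SD_first")
    })
  } else {
    universe <- Reduce(union, degsets)
    ranked <- lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      r <- rank_by_logfc(t[t$gene_id %in% degsets[[i]], , drop = FALSE],
                         if (genos[i] == "A") "LD_first" else "SD_first")
      miss <- setdiff(universe, names(r))
      c(r, stats::setNames(rep(length(r) + 1L, length(miss)), miss))
    })
  }
  universe <- sort(universe)
  if (length(universe) == 0L) {
    out <- data.frame(gene_id = character(0), rank_1 = integer(0),
                      rank_2 = integer(0), rank_3 = integer(0),
                      rank_4 = integer(0), score = integer(0),
                      lfc_1 = numeric(0), lfc_2 = numeric(0),
                      lfc_3 = numeric(0), lfc_4 = numeric(0),
                      deg_in_all = logical(0), stringsAsFactors = FALSE)
  } else {
    rmat <- vapply(ranked, function(r) unname(r[universe]), numeric(length(universe)))
    rmat <- matrix(rmat, nrow = length(universe))
    lmat <- vapply(tables, function(t) {
      t$log_fc[match(universe, t$gene_id)]
    }, numeric(length(universe)))
    lmat <- matrix(lmat, nrow = length(universe))
    in_all <- universe %in% Reduce(intersect, degsets)
    out <- data.frame(gene_id = universe,
                      rank_1 = as.integer(rmat[, 1]),
                      rank_2 = as.integer(rmat[, 2]),
                      rank_3 = as.integer(rmat[, 3]),
                      rank_4 = as.integer(rmat[, 4]),
                      score = as.integer(rowSums(rmat)),
                      lfc_1 = lmat[, 1], lfc_2 = lmat[, 2],
                      lfc_3 = lmat[, 3], lfc_4 = lmat[, 4],
                      deg_in_all = in_all, stringsAsFactors = FALSE)
    out <- out[order(out$score, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "comparisons") <- lapply(tables, function(t)
    list(genotype = attr(t, "genotype"), day = attr(t, "day"),
         time_of_day = attr(t, "time_of_day")))
  attr(out, "universe_policy") <- universe_policy
  out
}

#' Select top candidates from a contrast-score table
#'
#' Takes the `top_k` lowest-scoring genes, optionally requiring the planted
#' direction of a contrasting gene: logFC > 0 (LD-up) in both genotype-A
#' comparisons and logFC < 0 (SD-up) in both genotype-B comparisons. The sign
#' gate is applied before truncation, so inconsistent genes do not occupy
#' candidate slots.
#'
#' @param scores output of [contrast_score()] (already sorted).
#' @param top_k number of candidates to keep (> 0).
#' @param require_sign_consistency apply the direction gate (default TRUE).
#' @return the selected rows of `scores` (possibly fewer than `top_k`).
#' @export
select_candidates <- function(scores, top_k, require_sign_consistency = TRUE) {
  if (!is.numeric(top_k) || length(top_k) != 1L || is.na(top_k) || top_k <= 0)
    stop("top_k must be a positive integer", call. = FALSE)
  out <- scores
  if (require_sign_consistency && nrow(out) > 0L) {
    ok <- out$lfc_1 > 0 & out$lfc_2 > 0 & out$lfc_3 < 0 & out$lfc_4 < 0
    out <- out[ok, , drop = FALSE]
  }
  out <- utils::head(out, as.integer(top_k))
  rownames(out) <- NULL
  out
}
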