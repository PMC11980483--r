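#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row, gene ids in the first column (`gene_id`), one column
#' per sample, tab-separated, no quoting. Validates uniqueness of gene and
#' sample ids and that every count is a nonnegative number, reporting the
#' offending row/column on failure.
#'
#' @param path file path.
#' @return integer matrix with gene ids as row names, sample ids as column
#'   names.
#' @export
read_counts_tsv <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("counts TSV needs a gene_id column plus at least one sample column",
         call. = FALSE)
  gene_id <- as.character(raw[[1]])
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  sample_id <- colnames(raw)[-1]
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in ", path, call. = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(col) | col < 0)
    if (length(bad))
      stop(sprintf(
        "invalid count at data row %d, column '%s' in %s: '%s' (must be a nonnegative number)",
        bad[1], sample_id[j], path, m[bad[1], j]), call. = FALSE)
  }
  storage.mode(m) <- "numeric"
  if (any(m != round(m)))
    stop("non-integer count values in ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_id, sample_id)
  m
}

#' Write a count matrix as TSV
#'
#' First column `gene_id`, remaining columns the samples; lossless round
#' trip with [read_counts_tsv()].
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_columns <- c("sample_id", "genotype", "photoperiod", "day",
                    "time_of_day", "replicate")

#' Read a sample design table from TSV
#'
#' Requires columns `sample_id`, `genotype`, `photoperiod`, `day`,
#' `time_of_day`, `replicate`; validates factor levels, uniqueness of sample
#' ids and of (genotype, photoperiod, day, time_of_day, replicate) tuples.
#'
#' @param path file path.
#' @return data.frame in canonical column order.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(design_columns, colnames(d))
  if (length(missing_cols))
    stop("design TSV ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- d[, design_columns]
  validate_design(d)
  d
}

validate_design <- function(d) {
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample ids in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(d$photoperiod %in% c("LD", "SD")))
    stop("photoperiod must be 'LD' or 'SD'", call. = FALSE)
  if (!all(d$time_of_day %in% c("morning", "afternoon")))
    stop("time_of_day must be 'morning' or 'afternoon'", call. = FALSE)
  if (!is.numeric(d$day) || anyNA(d$day))
    stop("day must be numeric (days after sowing)", call. = FALSE)
  tup <- interaction(d$genotype, d$photoperiod, d$day, d$time_of_day,
                     d$replicate, drop = TRUE)
  if (anyDuplicated(tup))
    stop("duplicate (genotype, photoperiod, day, time_of_day, replicate) ",
         "tuples in design", call. = FALSE)
  invisible(d)
}

#' Write a design table as TSV
#' @param design data.frame as from [design_table()].
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design[, design_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a count matrix and design table describe the same samples
#'
#' @param counts genes x samples matrix.
#' @param design design table.
#' @return invisibly TRUE; errors name any mismatched sample ids.
#' @export
validate_experiment <- function(counts, design) {
  validate_design(design)
  missing_in_counts <- setdiff(design$sample_id, colnames(counts))
  if (length(missing_in_counts))
    stop("design sample id(s) absent from counts: ",
         paste(missing_in_counts, collapse = ", "), call. = FALSE)
  if (any(counts < 0))
    stop("negative values in count matrix", call. = FALSE)
  invisible(TRUE)
}

#' Read/write truth labels
#'
#' Planted gene class labels produced by [simulate_experiment()].
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `class`, `direction`.
#' @export
read_truth_tsv <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class") %in% colnames(t)))
    stop("truth TSV needs gene_id and class columns", call. = FALSE)
  t
}

#' @rdname read_truth_tsv
#' @param truth data.frame with `gene_id`, `class`, `direction`.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write per-comparison differential tables
#'
#' Columns `gene_id`, `log_fc`, `base_mean`, `p_raw`, `fdr`, `is_deg`. The
#' comparison key is not stored in the file; supply it on read so that
#' [contrast_score()] can validate table compatibility.
#'
#' @param path file path.
#' @param genotype,day,time_of_day comparison key to attach as attributes.
#' @return data.frame as produced by [de_test()].
#' @export
read_de_tsv <- function(path, genotype = NA, day = NA, time_of_day = NA) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log_fc", "base_mean", "p_raw", "fdr", "is_deg")
  missing_cols <- setdiff(need, colnames(t))
  if (length(missing_cols))
    stop("differential table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  t$is_deg <- as.logical(t$is_deg)
  attr(t, "genotype") <- genotype
  attr(t, "day") <- day
  attr(t, "time_of_day") <- time_of_day
  t
}

#' @rdname read_de_tsv
#' @param table differential table from [de_test()].
#' @export
write_de_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
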