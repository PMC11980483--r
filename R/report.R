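#' Combine morning and afternoon candidate sets
#'
#' Union of the two diurnal candidate sets with inclusion-exclusion
#' accounting: n_union = n_morning + n_afternoon - n_both. Each gene is
#' labelled by its dataset of origin (`morning`, `afternoon`, or `both`).
#'
#' @param morning,afternoon character vectors of gene ids (or data.frames
#'   with a `gene_id` column, e.g. from [select_candidates()]).
#' @return an object of class `candidate_set`: a list with `table`
#'   (data.frame `gene_id`, `origin`, sorted by gene id) and counts
#'   `n_morning`, `n_afternoon`, `n_both`, `n_union`.
#' @examples
#' cs <- combine_diurnal(c("g1", "g2"), c("g2", "g3"))
#' cs$n_union  # 3
#' @export
combine_diurnal <- function(morning, afternoon) {
  as_ids <- function(x) {
    if (is.data.frame(x)) x <- x$gene_id
    if (is.null(x)) x <- character(0)
    unique(as.character(x))
  }
  m <- as_ids(morning)
  a <- as_ids(afternoon)
  both <- intersect(m, a)
  all_ids <- sort(union(m, a))
  origin <- ifelse(all_ids %in% both, "both",
                   ifelse(all_ids %in% m, "morning", "afternoon"))
  out <- list(
    table = data.frame(gene_id = all_ids, origin = origin,
                       stringsAsFactors = FALSE),
    n_morning = length(m),
    n_afternoon = length(a),
    n_both = length(both),
    n_union = length(all_ids)
  )
  class(out) <- "candidate_set"
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "Candidate set: %d morning + %d afternoon - %d shared = %d genes\n",
    x$n_morning, x$n_afternoon, x$n_both, x$n_union))
  invisible(x)
}

#' Recovery metrics against planted truth
#'
#' Precision, recall and F1 of a candidate gene set against the genes whose
#' planted class is `"contrast"`. With zero predictions, precision is
#' reported as 0 with `precision_undefined = TRUE` rather than NaN (and a
#' warning), so downstream checks stay machine-readable.
#'
#' @param candidate_ids character vector of predicted gene ids.
#' @param truth data.frame with `gene_id` and `class` columns.
#' @return list with `n_predicted`, `n_truth`, `tp`, `precision`, `recall`,
#'   `f1`, `precision_undefined`.
#' @export
recovery_metrics <- function(candidate_ids, truth) {
  pos <- truth$gene_id[truth$class == "contrast"]
  candidate_ids <- unique(as.character(candidate_ids))
  tp <- length(intersect(candidate_ids, pos))
  undefined <- length(candidate_ids) == 0L
  if (undefined)
    warning("empty candidate set: precision reported as 0", call. = FALSE)
  precision <- if (undefined) 0 else tp / length(candidate_ids)
  recall <- if (length(pos) == 0L) NA_real_ else tp / length(pos)
  f1 <- if (!is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  list(n_predicted = length(candidate_ids), n_truth = length(pos), tp = tp,
       precision = precision, recall = recall, f1 = f1,
       precision_undefined = undefined)
}

#' Write the final candidate report
#'
#' Emits the candidate table as TSV (gene id, origin, per-dataset rank-sum
#' score and per-comparison logFC), a machine-readable JSON run summary, and
#' — when planted truth is supplied — appends recovery metrics to the
#' summary.
#'
#' @param candidates a `candidate_set` from [combine_diurnal()].
#' @param morning_scores,afternoon_scores the [contrast_score()] tables the
#'   candidates were drawn from; every candidate id must appear in the score
#'   table of its dataset(s) of origin.
#' @param truth optional truth table (`gene_id`, `class`).
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix (default `"candidates"`).
#' @return invisibly, a list with `table` (the written data.frame), `summary`
#'   (the JSON payload as a list) and the two file `paths`.
#' @export
write_candidate_report <- function(candidates, morning_scores,
                                   afternoon_scores, truth = NULL,
                                   out_dir = ".", prefix = "candidates") {
  stopifnot(inherits(candidates, "candidate_set"))
  tab <- candidates$table
  need_m <- tab$gene_id[tab$origin %in% c("morning", "both")]
  need_a <- tab$gene_id[tab$origin %in% c("afternoon", "both")]
  bad <- c(setdiff(need_m, morning_scores$gene_id),
           setdiff(need_a, afternoon_scores$gene_id))
  if (length(bad))
    stop("candidate ids missing from score tables: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  pick <- function(scores, ids, col) scores[[col]][match(ids, scores$gene_id)]
  out <- data.frame(
    gene_id = tab$gene_id,
    origin = tab$origin,
    morning_score = pick(morning_scores, tab$gene_id, "score"),
    afternoon_score = pick(afternoon_scores, tab$gene_id, "score"),
    morning_lfc_A1 = pick(morning_scores, tab$gene_id, "lfc_1"),
    morning_lfc_A2 = pick(morning_scores, tab$gene_id, "lfc_2"),
    morning_lfc_B1 = pick(morning_scores, tab$gene_id, "lfc_3"),
    morning_lfc_B2 = pick(morning_scores, tab$gene_id, "lfc_4"),
    afternoon_lfc_A1 = pick(afternoon_scores, tab$gene_id, "lfc_1"),
    afternoon_lfc_A2 = pick(afternoon_scores, tab$gene_id, "lfc_2"),
    afternoon_lfc_B1 = pick(afternoon_scores, tab$gene_id, "lfc_3"),
    afternoon_lfc_B2 = pick(afternoon_scores, tab$gene_id, "lfc_4"),
    stringsAsFactors = FALSE
  )
  summary <- list(
    n_morning = candidates$n_morning,
    n_afternoon = candidates$n_afternoon,
    n_both = candidates$n_both,
    n_union = candidates$n_union
  )
  if (!is.null(truth)) {
    out$class <- truth$class[match(out$gene_id, truth$gene_id)]
    summary$metrics <- recovery_metrics(tab$gene_id, truth)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv_path <- file.path(out_dir, paste0(prefix, ".tsv"))
  json_path <- file.path(out_dir, paste0(prefix, "_summary.json"))
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(table = out, summary = summary,
                 paths = c(tsv = tsv_path, json = json_path)))
}

#' Read a written candidate table back as a candidate set
#'
#' Inverse of the TSV part of [write_candidate_report()]: reconstructs the
#' `candidate_set` (membership and counts) from the file.
#'
#' @param path path to a candidates TSV.
#' @return a `candidate_set`.
#' @export
read_candidate_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  combine_diurnal(tab$gene_id[tab$origin %in% c("morning", "both")],
                  tab$gene_id[tab$origin %in% c("afternoon", "both")])
}
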