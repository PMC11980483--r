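#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one input mode must be
#' supplied: a [sim_config()] for synthetic mode, or paths to a counts TSV
#' and a design TSV for user data.
#'
#' @param sim a [sim_config()] (synthetic mode), or NULL.
#' @param counts_path,design_path input TSVs (real-data mode), or NULL.
#' @param truth_path optional truth TSV for recovery metrics in real-data
#'   mode.
#' @param fdr_threshold FDR cutoff for DEG status (default 0.05).
#' @param min_mean,max_cv expression filter thresholds (see
#'   [filter_genes()]).
#' @param universe_policy rank universe policy (see [contrast_score()]).
#' @param top_k candidates kept per diurnal dataset (default 25).
#' @param out_dir output directory for stage artifacts.
#' @param verbose print stage progress to stderr.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, counts_path = NULL,
                            design_path = NULL, truth_path = NULL,
                            fdr_threshold = 0.05, min_mean = 5, max_cv = 1,
                            universe_policy = c("intersection", "penalty"),
                            top_k = 25, out_dir = "photorank_out",
                            verbose = FALSE) {
  universe_policy <- match.arg(universe_policy)
  synthetic <- !is.null(sim)
  real <- !is.null(counts_path) || !is.null(design_path)
  if (synthetic && real)
    stop("configuration error: supply either a sim_config or data paths, ",
         "not both", call. = FALSE)
  if (!synthetic && (is.null(counts_path) || is.null(design_path)))
    stop("configuration error: supply a sim_config, or both counts_path ",
         "and design_path", call. = FALSE)
  if (synthetic) validate_sim_config(sim)
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("configuration error: fdr_threshold must lie in (0, 1]",
         call. = FALSE)
  if (min_mean < 0 || max_cv < 0)
    stop("configuration error: filter thresholds must be >= 0", call. = FALSE)
  if (top_k <= 0)
    stop("configuration error: top_k must be positive", call. = FALSE)
  structure(list(sim = sim, counts_path = counts_path,
                 design_path = design_path, truth_path = truth_path,
                 fdr_threshold = fdr_threshold, min_mean = min_mean,
                 max_cv = max_cv, universe_policy = universe_policy,
                 top_k = as.integer(top_k), out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

pipe_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}

config_echo <- function(config) {
  echo <- unclass(config)
  if (!is.null(echo$sim)) echo$sim <- unclass(echo$sim)
  echo$verbose <- NULL
  echo
}

#' Run the full contrast-screening pipeline
#'
#' Stages: (1) simulate or load counts/design; (2) LD-vs-SD differential
#' expression at each genotype's two later (inductive) sampling days, for
#' morning and afternoon separately — eight comparisons in all; (3) per
#' dataset, expression filtering, rank-sum contrast scoring and candidate
#' selection; (4) morning/afternoon union and final report. All stage
#' outputs plus a provenance record are written under `config$out_dir`;
#' running the same configuration twice produces identical artifacts. On a
#' stage failure, partial outputs are kept next to a `FAILED` marker naming
#' the stage, and the error is re-thrown.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `counts`, `design`, `truth`, `de_tables`
#'   (named list of eight), `scores` (morning/afternoon), `candidates`
#'   (the combined `candidate_set`), `report` (table + summary), and
#'   `stage_counts` (genes surviving each stage per dataset).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  provenance <- list(
    package = "photorank",
    version = as.character(utils::packageVersion("photorank")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = if (is.null(config$sim)) "real" else "synthetic",
    config = config_echo(config)
  )
  write_provenance <- function(status) {
    provenance$status <- status
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result <- tryCatch({
    if (!is.null(config$sim)) {
      stage <- "simulate"
      pipe_log(config, "simulating experiment (seed ", config$sim$seed, ")")
      sim <- simulate_experiment(config$sim)
      counts <- sim$counts
      design <- sim$design
      truth <- sim$truth
      write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
      write_design_tsv(design, file.path(out_dir, "design.tsv"))
      write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    } else {
      stage <- "load"
      pipe_log(config, "loading ", config$counts_path)
      counts <- read_counts_tsv(config$counts_path)
      design <- read_design_tsv(config$design_path)
      validate_experiment(counts, design)
      truth <- if (!is.null(config$truth_path))
        read_truth_tsv(config$truth_path) else NULL
    }

    stage <- "de"
    windows <- lapply(split(design$day, design$genotype), induction_days)
    de_tables <- list()
    for (tod in c("morning", "afternoon")) {
      for (geno in names(windows)) {
        for (day in windows[[geno]]) {
          key <- sprintf("%s_%s_d%02d", tod, geno, day)
          pipe_log(config, "differential expression: ", key)
          tab <- de_test(counts, design, geno, day, tod,
                         fdr_threshold = config$fdr_threshold)
          write_de_tsv(tab, file.path(out_dir, paste0("de_", key, ".tsv")))
          de_tables[[key]] <- tab
        }
      }
    }

    stage <- "contrast"
    scores <- list()
    selected <- list()
    stage_counts <- list()
    for (tod in c("morning", "afternoon")) {
      window_design <- design[
        design$time_of_day == tod &
          ((design$genotype == "A" & design$day %in% windows[["A"]]) |
           (design$genotype == "B" & design$day %in% windows[["B"]])), ,
        drop = FALSE]
      eligible <- filter_genes(counts, window_design,
                               min_mean = config$min_mean,
                               max_cv = config$max_cv)
      tabs <- de_tables[grep(paste0("^", tod, "_"), names(de_tables))]
      sc <- contrast_score(unname(tabs), eligible = eligible,
                           universe_policy = config$universe_policy)
      sel <- select_candidates(sc, top_k = config$top_k)
      write_de_scores <- file.path(out_dir, paste0("scores_", tod, ".tsv"))
      utils::write.table(sc, write_de_scores, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      scores[[tod]] <- sc
      selected[[tod]] <- sel
      stage_counts[[tod]] <- c(total = nrow(counts),
                               eligible = length(eligible),
                               scored = nrow(sc), selected = nrow(sel))
    }

    stage <- "report"
    candidates <- combine_diurnal(selected$morning, selected$afternoon)
    rep_out <- write_candidate_report(candidates, scores$morning,
                                      scores$afternoon, truth = truth,
                                      out_dir = out_dir)
    sc_path <- file.path(out_dir, "stage_counts.json")
    jsonlite::write_json(stage_counts, sc_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write_provenance("OK")
    pipe_log(config, sprintf(
      "done: %d morning + %d afternoon - %d shared = %d candidates",
      candidates$n_morning, candidates$n_afternoon, candidates$n_both,
      candidates$n_union))
    list(counts = counts, design = design, truth = truth,
         de_tables = de_tables, scores = scores, candidates = candidates,
         report = rep_out, stage_counts = stage_counts)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    write_provenance(paste0("FAILED at stage ", stage))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
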