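#' Consensus pool across selector runs
#'
#' Counts how often each item was chosen across a collection of selection
#' runs (e.g. 3 selectors x 5 folds) and keeps the items selected at least
#' `min_count` times ("selected more than once" at the default of 2).
#'
#' @param runs list of character vectors of selected items.
#' @param min_count minimum selection count for the consensus pool.
#' @return A `consensus_report`: `counts` (named integer vector, decreasing)
#'   and `pool` (character vector).
#' @export
consensus_features <- function(runs, min_count = 2) {
  if (length(runs) == 0) stop("no runs supplied")
  all_items <- unlist(runs)
  counts <- sort(base::table(all_items), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts,
                 pool = names(counts)[counts >= min_count],
                 min_count = min_count, n_runs = length(runs)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus_report: ", length(x$counts), " items counted over ",
      x$n_runs, " runs; pool of ", length(x$pool), " (count >= ",
      x$min_count, ")\n", sep = "")
  invisible(x)
}

#' Sweep the cost weight and map the accuracy-time frontier
#'
#' For each lambda in the grid, runs cost-sensitive CFS on the table
#' restricted to the candidate pool (the correlation cache is computed once
#' and reused). Identical selected sets are deduplicated, keeping the
#' smallest lambda that produced each; every unique set is then priced with
#' the cost table and scored by standard stratified k-fold Hand-Till AUC.
#'
#' @param table a `feature_table`.
#' @param pool candidate items (e.g. a consensus pool), subset of the table.
#' @param costs a `cost_table`.
#' @param lambdas ascending numeric grid starting at 0; default 0 to 0.05 in
#'   steps of 0.0005.
#' @param backend a `classifier_backend` for the AUC evaluation.
#' @param seed RNG seed for the cross-validation.
#' @param k folds for the AUC evaluation.
#' @param mode association mode for the CFS cache.
#' @return A data.frame of frontier points: `lambda`, `n_items`, `items`
#'   ("+"-joined), `total_cost_seconds`, `mean_auc`, sorted by lambda.
#' @export
lambda_sweep <- function(table, pool, costs,
                         lambdas = seq(0, 0.05, by = 5e-4),
                         backend = rf_backend(), seed = 1, k = 5,
                         mode = "fselector") {
  missing <- setdiff(pool, items_of(table))
  if (length(missing))
    stop("pool item(s) not in table: ", paste(missing, collapse = ", "))
  lambdas <- sort(unique(lambdas))
  if (any(lambdas < 0)) stop("lambdas must be >= 0")
  sub <- restrict_items(table, pool)
  cache <- build_correlation_cache(sub, mode = mode)
  sets <- list(); set_lambda <- numeric(0)
  for (lam in lambdas) {
    res <- cost_cfs_select(sub, merit_params(lam, costs), mode = mode,
                           cache = cache)
    its <- sort(res$items)
    if (length(its) == 0) {
      warning("empty selection at lambda = ", lam)
      next
    }
    key <- paste(its, collapse = "+")
    if (!key %in% names(sets)) {
      sets[[key]] <- its
      set_lambda[key] <- lam
    }
  }
  rows <- lapply(names(sets), function(key) {
    its <- sets[[key]]
    cv <- standard_cv_auc(table, its, k = k, backend = backend, seed = seed)
    data.frame(lambda = set_lambda[key], n_items = length(its),
               items = key, total_cost_seconds = total_cost(its, costs),
               mean_auc = cv$overall_mean_auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lambda), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pareto front of frontier points
#'
#' Keeps the points not dominated in the (total time, AUC) plane: a point is
#' dropped when another point has at least its AUC at strictly lower cost, or
#' strictly higher AUC at no more cost.
#'
#' @param points data.frame with `total_cost_seconds` and `mean_auc` columns
#'   (as produced by [lambda_sweep()]).
#' @return The non-dominated rows, sorted by cost.
#' @export
pareto_front <- function(points) {
  if (nrow(points) == 0) stop("no points")
  keep <- vapply(seq_len(nrow(points)), function(i) {
    ci <- points$total_cost_seconds[i]; ai <- points$mean_auc[i]
    !any((points$mean_auc >= ai & points$total_cost_seconds < ci) |
           (points$mean_auc > ai & points$total_cost_seconds <= ci))
  }, logical(1))
  out <- points[keep, , drop = FALSE]
  out <- out[order(out$total_cost_seconds, -out$mean_auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param data either a `synthetic_spec` or a list
#'   `list(features = path, label_column = name, costs = path)` of CSV paths.
#' @param selectors subset of `c("cfs", "consistency", "boruta")`.
#' @param folds cross-validation folds.
#' @param lambda_grid ascending grid starting at 0.
#' @param min_count consensus threshold.
#' @param seed master seed; all stage seeds derive from it.
#' @param backend classifier backend for AUC evaluation.
#' @param boruta_backend importance backend for the Boruta selector.
#' @param boruta_max_iter Boruta iteration cap.
#' @param mode association mode for CFS.
#' @param output_dir optional directory for the report bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = synthetic_spec(),
                            selectors = c("cfs", "consistency", "boruta"),
                            folds = 5,
                            lambda_grid = seq(0, 0.05, by = 5e-4),
                            min_count = 2, seed = 1,
                            backend = rf_backend(),
                            boruta_backend = rf_importance_backend(),
                            boruta_max_iter = 100,
                            mode = "fselector",
                            output_dir = NULL) {
  selectors <- match.arg(selectors, c("cfs", "consistency", "boruta"),
                         several.ok = TRUE)
  structure(list(data = data, selectors = selectors, folds = folds,
                 lambda_grid = lambda_grid, min_count = min_count,
                 seed = as.integer(seed), backend = backend,
                 boruta_backend = boruta_backend,
                 boruta_max_iter = boruta_max_iter, mode = mode,
                 output_dir = output_dir),
            class = "pipeline_config")
}

resolve_pipeline_data <- function(config) {
  if (inherits(config$data, "synthetic_spec")) {
    gen <- generate_assessment_data(config$data)
    list(table = gen$table, costs = gen$costs, truth = gen$truth)
  } else if (is.list(config$data) && !is.null(config$data$features)) {
    tab <- load_feature_table(config$data$features,
                              config$data$label_column %||% "severity")
    costs <- if (!is.null(config$data$costs))
      load_cost_table(config$data$costs) else default_cost_table()
    list(table = tab, costs = costs, truth = NULL)
  } else stop("config$data must be a synthetic_spec or a list of paths")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_selector <- function(id, config, sub_seed) {
  switch(id,
    cfs = function(tab) cfs_select(tab, mode = config$mode),
    consistency = function(tab) consistency_select(tab),
    boruta = function(tab) {
      res <- boruta_select(tab, importance_backend = config$boruta_backend,
                           max_iter = config$boruta_max_iter,
                           seed = sub_seed)
      res$confirmed
    },
    stop("unknown selector: ", id))
}

#' Run the full accuracy-cost optimisation pipeline
#'
#' Orchestrates the whole analysis: (1) each configured selector is run under
#' feature-selection-aware cross-validation, giving per-fold item sets and
#' AUCs; (2) the selected sets across all selectors and folds are pooled by
#' [consensus_features()]; (3) the cost weight is swept over the grid with
#' cost-sensitive CFS on the consensus pool, pricing and scoring each unique
#' set ([lambda_sweep()]); (4) the Pareto front of the accuracy-time
#' trade-off is extracted. Fully reproducible given the config seed. When
#' `output_dir` is set, writes `consensus_counts.csv`, `frontier.csv`,
#' `pareto.csv`, `report.json` and `run.log`.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list: `config_summary`, `selector_cv` (list of
#'   `cv_result` per selector), `consensus`, `frontier`, `pareto`, `seed`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "data"
  report <- tryCatch({
    dat <- resolve_pipeline_data(config)
    seeds <- withr::with_seed(config$seed,
      sample.int(.Machine$integer.max,
                 length(config$selectors) + 1))

    stage <- "selector_cv"
    selector_cv <- list()
    runs <- list()
    for (i in seq_along(config$selectors)) {
      id <- config$selectors[i]
      cv <- fs_fold_cv(dat$table, make_selector(id, config, seeds[i]),
                       k = config$folds, backend = config$backend,
                       seed = seeds[i])
      selector_cv[[id]] <- cv
      runs <- c(runs, cv$per_fold$items)
    }

    stage <- "consensus"
    consensus <- consensus_features(runs, min_count = config$min_count)
    if (length(consensus$pool) < 2)
      stop("consensus pool has fewer than 2 items; lower min_count")

    stage <- "lambda_sweep"
    frontier <- lambda_sweep(dat$table, consensus$pool, dat$costs,
                             lambdas = config$lambda_grid,
                             backend = config$backend,
                             seed = seeds[length(seeds)],
                             k = config$folds, mode = config$mode)

    stage <- "pareto"
    pareto <- pareto_front(frontier)

    list(config_summary = list(selectors = config$selectors,
                               folds = config$folds,
                               lambda_grid = range(config$lambda_grid),
                               n_lambdas = length(config$lambda_grid),
                               min_count = config$min_count,
                               mode = config$mode,
                               backend = config$backend$id,
                               seed = config$seed),
         selector_cv = selector_cv,
         consensus = consensus,
         frontier = frontier,
         pareto = pareto,
         truth = dat$truth,
         seed = config$seed)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_pipeline_report(report,
                                                         config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$seed, ")\n", sep = "")
  for (id in names(x$selector_cv))
    cat(sprintf("  %-12s mean AUC %.3f (%s items/fold)\n", id,
                x$selector_cv[[id]]$overall_mean_auc,
                paste(x$selector_cv[[id]]$per_fold$n_items, collapse = "/")))
  cat("  consensus pool:", length(x$consensus$pool), "items\n")
  cat("  frontier:", nrow(x$frontier), "unique sets; Pareto front:",
      nrow(x$pareto), "\n")
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(item = names(report$consensus$counts),
                              count = unname(report$consensus$counts)),
                   file.path(dir, "consensus_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$frontier, file.path(dir, "frontier.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$pareto, file.path(dir, "pareto.csv"),
                   row.names = FALSE, quote = FALSE)
  json <- list(
    config = report$config_summary,
    selector_cv = lapply(report$selector_cv, function(cv)
      list(mean_auc = cv$overall_mean_auc,
           per_fold = lapply(seq_len(nrow(cv$per_fold)), function(i)
             list(fold = cv$per_fold$fold[i],
                  auc = cv$per_fold$auc[i],
                  items = cv$per_fold$items[[i]])))),
    consensus_pool = report$consensus$pool,
    frontier = report$frontier,
    pareto = report$pareto)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("seed: %d", report$seed),
               sprintf("selectors: %s",
                       paste(report$config_summary$selectors,
                             collapse = ",")),
               sprintf("backend: %s", report$config_summary$backend),
               sprintf("package: cfaopt %s",
                       as.character(utils::packageVersion("cfaopt")))),
             file.path(dir, "run.log"))
  invisible(dir)
}
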