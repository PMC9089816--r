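#' Inconsistency rate of an item subset
#'
#' Rows are grouped by their joint value pattern on the subset (continuous
#' items are discretized into `n_bins` equal-frequency bins first). Within
#' each pattern the inconsistency count is the pattern size minus the largest
#' single-class count; the rate is the summed counts over the number of rows.
#' A rate of 0 means the subset's value patterns determine the class label
#' exactly.
#'
#' @param table a `feature_table`.
#' @param subset non-empty character vector of item names.
#' @param n_bins bins for discretizing continuous items.
#' @return Value in `[0, 1]`.
#' @export
inconsistency_rate <- function(table, subset, n_bins = 5) {
  if (length(subset) == 0) stop("empty subset")
  missing <- setdiff(subset, items_of(table))
  if (length(missing))
    stop("item(s) not in table: ", paste(missing, collapse = ", "))
  cols <- lapply(subset, function(nm) {
    v <- table$data[[nm]]
    if (table$kinds[[nm]] == "continuous")
      suppressWarnings(discretize(v, n_bins)) else v
  })
  pattern <- do.call(paste, c(cols, sep = "\r"))
  counts <- base::table(pattern, table$labels)
  sum(rowSums(counts) - apply(counts, 1, max)) / nrow(table$data)
}

#' Consistency-based feature selection
#'
#' Forward best-first search maximising `1 - inconsistency_rate`. Because
#' adding items can never increase inconsistency, score ties are pervasive;
#' the search's earlier-generated tie-break resolves them toward smaller
#' subsets, so the result is a smallest subset (along the search path) at the
#' best attainable consistency.
#'
#' @param table a `feature_table` with >= 2 items.
#' @param max_stale best-first stopping patience.
#' @param n_bins bins for discretizing continuous items.
#' @return A `selection_result`.
#' @export
consistency_select <- function(table, max_stale = 5, n_bins = 5) {
  if (length(items_of(table)) < 2) stop("need at least 2 items")
  res <- best_first_search(
    function(s) 1 - inconsistency_rate(table, s, n_bins = n_bins),
    items_of(table), max_stale = max_stale)
  res$evaluator_id <- "consistency"
  res
}

# ---- importance backends ---------------------------------------------------

#' Random-forest permutation-importance backend
#'
#' The default importance backend for [boruta_select()]: a seeded
#' `ranger` forest (single-threaded for reproducibility) returning
#' permutation importances.
#'
#' @param num_trees number of trees.
#' @return A function(data.frame X, factor y, seed) -> named numeric
#'   importance vector.
#' @export
rf_importance_backend <- function(num_trees = 500) {
  function(X, y, seed) {
    fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                          importance = "permutation", seed = seed,
                          num.threads = 1, respect.unordered.factors = TRUE)
    fit$variable.importance
  }
}

#' Fast univariate importance backend
#'
#' A lightweight surrogate for tests and quick runs: per-feature
#' Kruskal-Wallis rank statistic of the feature against the class, computed
#' on a bootstrap resample so repeated iterations see sampling variability
#' (as a forest backend would).
#'
#' @return A function(X, y, seed) -> named numeric importance vector.
#' @export
kruskal_importance_backend <- function() {
  function(X, y, seed) {
    idx <- withr::with_seed(seed,
                            sample.int(nrow(X), nrow(X), replace = TRUE))
    yb <- y[idx]
    vapply(X, function(v) {
      vb <- v[idx]
      if (length(unique(vb)) < 2) return(0)
      unname(stats::kruskal.test(vb, yb)$statistic)
    }, numeric(1))
  }
}

#' Boruta-style shadow-feature selection
#'
#' Each iteration appends one row-shuffled "shadow" copy of every undecided
#' real feature, fits the importance backend on real + shadow features, and
#' records a "hit" for each undecided feature whose importance exceeds the
#' maximum shadow importance. After a warm-up, each undecided feature's hit
#' count is tested against Binomial(iterations, 0.5) with two one-sided tails,
#' Bonferroni-corrected over the currently undecided features: significantly
#' more hits than chance confirms the feature, significantly fewer rejects
#' it. Features still undecided at `max_iter` remain tentative.
#'
#' @param table a `feature_table`.
#' @param importance_backend function(X, y, seed) -> named importance vector;
#'   defaults to [rf_importance_backend()].
#' @param alpha significance level for the binomial tests.
#' @param max_iter maximum iterations.
#' @param seed RNG seed controlling shadow shuffles and backend fits.
#' @param warmup iterations before testing begins.
#' @return An object of class `boruta_result` with `confirmed`, `rejected`,
#'   `tentative` (disjoint sets partitioning the pool), `history` (one row per
#'   iteration x feature with importance, shadow max and hit flag) and
#'   `iterations_run`.
#' @export
boruta_select <- function(table, importance_backend = rf_importance_backend(),
                          alpha = 0.05, max_iter = 100, seed = 1,
                          warmup = 5) {
  items <- items_of(table)
  y <- table$labels
  confirmed <- character(0); rejected <- character(0)
  undecided <- items
  hits <- stats::setNames(integer(length(items)), items)
  tested <- stats::setNames(integer(length(items)), items)
  history <- list()
  iter <- 0L
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, max(max_iter, 1) * 2))
  while (length(undecided) > 0 && iter < max_iter) {
    iter <- iter + 1L
    X <- table$data[, undecided, drop = FALSE]
    shadows <- withr::with_seed(sub_seeds[2 * iter - 1],
      as.data.frame(lapply(X, sample), check.names = FALSE))
    names(shadows) <- paste0(".shadow.", names(X))
    imp <- importance_backend(cbind(X, shadows), y, sub_seeds[2 * iter])
    shadow_max <- max(imp[names(shadows)])
    real_imp <- imp[undecided]
    hit <- real_imp > shadow_max
    hits[undecided] <- hits[undecided] + as.integer(hit)
    tested[undecided] <- tested[undecided] + 1L
    history[[iter]] <- data.frame(iteration = iter, item = undecided,
                                  importance = unname(real_imp),
                                  shadow_max = shadow_max,
                                  hit = unname(hit),
                                  stringsAsFactors = FALSE)
    if (iter > warmup) {
      m <- length(undecided)
      p_more <- stats::pbinom(hits[undecided] - 1L, tested[undecided], 0.5,
                              lower.tail = FALSE)
      p_less <- stats::pbinom(hits[undecided], tested[undecided], 0.5)
      conf <- undecided[pmin(1, p_more * m) < alpha]
      rej <- undecided[pmin(1, p_less * m) < alpha]
      confirmed <- c(confirmed, conf)
      rejected <- c(rejected, rej)
      undecided <- setdiff(undecided, c(conf, rej))
    }
  }
  structure(list(confirmed = confirmed, rejected = rejected,
                 tentative = undecided,
                 history = do.call(rbind, history),
                 iterations_run = iter),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("boruta_result: ", length(x$confirmed), " confirmed, ",
      length(x$rejected), " rejected, ", length(x$tentative),
      " tentative after ", x$iterations_run, " iteration(s)\n", sep = "")
  invisible(x)
}
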