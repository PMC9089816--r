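#' Cost-weighting parameters for the cost-sensitive merit
#'
#' @param lambda cost weight, >= 0; 0 recovers plain CFS.
#' @param costs a `cost_table`; costs enter the penalty raw, in seconds, so
#'   meaningful lambda values live on the 0-0.05 scale against second-scale
#'   administration times.
#' @return An object of class `merit_params`.
#' @export
merit_params <- function(lambda = 0, costs = default_cost_table()) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be a single value >= 0")
  stopifnot(inherits(costs, "cost_table"))
  structure(list(lambda = lambda, costs = costs), class = "merit_params")
}

#' CFS merit of an item subset
#'
#' The correlation-based feature selection heuristic
#' \deqn{Merit(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}}
#' where `k` is the subset size, \eqn{\bar r_{cf}} the mean feature-class
#' association and \eqn{\bar r_{ff}} the mean association over all unordered
#' within-subset pairs. Larger for subsets that correlate with the class while
#' being mutually uncorrelated; the denominator penalises large subsets.
#'
#' @param subset non-empty character vector of item names.
#' @param cache a `correlation_cache` covering the subset.
#' @return The merit value.
#' @export
merit <- function(subset, cache) {
  if (length(subset) == 0) stop("merit of an empty subset is undefined")
  missing <- setdiff(subset, cache$items)
  if (length(missing))
    stop("item(s) not in cache: ", paste(missing, collapse = ", "))
  k <- length(subset)
  rcf <- mean(cache$feature_class[subset])
  if (k == 1) return(unname(rcf))
  ff <- cache$feature_feature[subset, subset]
  rff <- mean(ff[upper.tri(ff)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Cost-sensitive merit
#'
#' Subtracts a mean administration-time penalty from the CFS merit:
#' \deqn{Merit(S) - \lambda\,\frac{\sum_{i \in S} C_i}{k}}
#' with \eqn{C_i} the per-item cost in seconds. At `lambda = 0` this is
#' exactly [merit()].
#'
#' @inheritParams merit
#' @param params a [merit_params()].
#' @return The penalised merit value.
#' @export
cost_merit <- function(subset, cache, params) {
  m <- merit(subset, cache)
  if (params$lambda == 0) return(m)
  m - params$lambda * sum(cost_lookup(params$costs, subset)) / length(subset)
}

subset_key <- function(idx) paste(idx, collapse = ",")

# lexicographic comparison of sorted name vectors; TRUE if a < b
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Forward best-first subset search
#'
#' Maintains an open list of scored subsets, seeded with every singleton.
#' Repeatedly expands the best-scoring open subset by adding each unused item,
#' and stops after `max_stale` consecutive expansions that fail to improve the
#' best score (or when the open list empties). Deterministic given the pool
#' order: score ties are broken toward the earlier-generated, then
#' lexicographically smaller, subset.
#'
#' @param evaluate function(character vector of items) -> numeric score.
#' @param items candidate item pool (order fixes tie-breaking).
#' @param max_stale non-improving expansions tolerated before stopping.
#' @return A `selection_result`: `items` (best subset found), `score`, `trace`
#'   (data.frame of expanded subsets and scores, in expansion order) and
#'   `evaluator_id`.
#' @export
best_first_search <- function(evaluate, items, max_stale = 5) {
  p <- length(items)
  if (p == 0) stop("empty candidate pool")
  eps <- 1e-12

  open_idx <- vector("list", 64); open_score <- numeric(64)
  open_gen <- integer(64); open_n <- 0L; gen <- 0L
  push <- function(idx, score) {
    open_n <<- open_n + 1L; gen <<- gen + 1L
    if (open_n > length(open_idx)) {
      length(open_idx) <<- 2L * open_n
      length(open_score) <<- 2L * open_n
      length(open_gen) <<- 2L * open_n
    }
    open_idx[[open_n]] <<- idx
    open_score[open_n] <<- score
    open_gen[open_n] <<- gen
  }
  pop_best <- function() {
    sc <- open_score[seq_len(open_n)]
    best <- which(sc == max(sc))
    i <- best[which.min(open_gen[best])]
    node <- list(idx = open_idx[[i]], score = open_score[i])
    open_idx[[i]] <<- open_idx[[open_n]]
    open_score[i] <<- open_score[open_n]
    open_gen[i] <<- open_gen[open_n]
    open_n <<- open_n - 1L
    node
  }

  seen <- new.env(hash = TRUE, parent = emptyenv())
  best_idx <- NULL; best_score <- -Inf
  consider_best <- function(idx, score) {
    if (score > best_score + eps) {
      best_idx <<- idx; best_score <<- score
      TRUE
    } else FALSE
  }

  for (i in seq_len(p)) {
    s <- evaluate(items[i])
    assign(subset_key(i), TRUE, envir = seen)
    push(i, s)
    consider_best(i, s)
  }

  trace_sets <- character(0); trace_scores <- numeric(0)
  stale <- 0L
  while (open_n > 0L && stale < max_stale) {
    node <- pop_best()
    trace_sets <- c(trace_sets, paste(items[node$idx], collapse = "+"))
    trace_scores <- c(trace_scores, node$score)
    improved <- FALSE
    for (j in setdiff(seq_len(p), node$idx)) {
      child <- sort(c(node$idx, j))
      key <- subset_key(child)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      s <- evaluate(items[child])
      push(child, s)
      if (consider_best(child, s)) improved <- TRUE
    }
    stale <- if (improved) 0L else stale + 1L
  }

  selection_result(items[best_idx], best_score,
                   trace = data.frame(subset = trace_sets,
                                      score = trace_scores,
                                      stringsAsFactors = FALSE),
                   evaluator_id = "best_first")
}

#' Exhaustive subset search (test oracle)
#'
#' Scores every non-empty subset of a small pool and returns the global
#' argmax; score ties go to the lexicographically smallest subset (shorter
#' prefixes win). Guarded to pools of at most 20 items.
#'
#' @inheritParams best_first_search
#' @return A `selection_result` (trace omitted).
#' @export
exhaustive_search <- function(evaluate, items) {
  p <- length(items)
  if (p == 0) stop("empty candidate pool")
  if (p > 20) stop("exhaustive search limited to pools of <= 20 items")
  eps <- 1e-12
  best_set <- NULL; best_score <- -Inf
  for (mask in seq_len(2^p - 1)) {
    sel <- sort(items[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L])
    s <- evaluate(sel)
    if (is.null(best_set) || s > best_score + eps ||
        (abs(s - best_score) <= eps && lex_less(sel, best_set))) {
      best_set <- sel; best_score <- s
    }
  }
  selection_result(best_set, best_score, evaluator_id = "exhaustive")
}

#' Construct a selection result
#' @param items selected item names.
#' @param score evaluator value at `items`.
#' @param trace optional data.frame of the search trace.
#' @param evaluator_id identifier of the evaluator/search that produced this.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(items, score, trace = NULL,
                             evaluator_id = "custom") {
  if (anyDuplicated(items)) stop("selected items must be unique")
  structure(list(items = items, score = score, trace = trace,
                 evaluator_id = evaluator_id),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (", x$evaluator_id, "): ", length(x$items),
      " item(s), score ", format(x$score, digits = 6), "\n", sep = "")
  cat("  ", paste(x$items, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation-based feature selection
#'
#' Builds the correlation cache for the table and runs a forward best-first
#' search over the CFS merit.
#'
#' @param table a `feature_table` with >= 2 items.
#' @param mode association mode, see [build_correlation_cache()].
#' @param max_stale best-first stopping patience.
#' @return A `selection_result`.
#' @export
cfs_select <- function(table, mode = "fselector", max_stale = 5) {
  if (length(items_of(table)) < 2) stop("need at least 2 items")
  cache <- build_correlation_cache(table, mode = mode)
  res <- best_first_search(function(s) merit(s, cache), items_of(table),
                           max_stale = max_stale)
  res$evaluator_id <- paste0("cfs/", mode)
  res
}

#' Cost-sensitive correlation-based feature selection
#'
#' As [cfs_select()] but the search maximises [cost_merit()]: merit minus
#' `lambda` times the mean per-item administration time. With `lambda = 0` the
#' search and its result score coincide with plain CFS.
#'
#' @inheritParams cfs_select
#' @param params a [merit_params()] carrying `lambda` and the cost table.
#' @param cache optional precomputed `correlation_cache` (reused across a
#'   lambda sweep).
#' @return A `selection_result`.
#' @export
cost_cfs_select <- function(table, params, mode = "fselector",
                            max_stale = 5, cache = NULL) {
  if (length(items_of(table)) < 2) stop("need at least 2 items")
  if (is.null(cache)) cache <- build_correlation_cache(table, mode = mode)
  res <- best_first_search(function(s) cost_merit(s, cache, params),
                           items_of(table), max_stale = max_stale)
  res$evaluator_id <- sprintf("costcfs/%s/lambda=%g", mode, params$lambda)
  res
}
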