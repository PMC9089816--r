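#' Binary rank-statistic AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted half (midrank handling); equivalent to
#' the Mann-Whitney statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present (", n1, " positive, ", n0, " negative)")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hand-Till multiclass AUC
#'
#' Extends binary AUC to three (or more) classes by averaging over unordered
#' class pairs: for a pair (i, j), rows of the two classes are extracted and
#' \eqn{\hat A(i,j) = [A(i|j) + A(j|i)]/2}, where `A(i|j)` is the binary AUC
#' of class i's score column separating i from j. The overall AUC is the mean
#' of \eqn{\hat A} over all pairs.
#'
#' @param score_matrix numeric matrix, one column per class (columns named by
#'   class) and one row per observation.
#' @param labels class labels; every class level present in `labels` must
#'   have a score column.
#' @return AUC in `[0, 1]`.
#' @export
hand_till_auc <- function(score_matrix, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  missing <- setdiff(classes, colnames(score_matrix))
  if (length(missing))
    stop("no score column for class: ", paste(missing, collapse = ", "))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  mean(vapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    rows <- labels %in% pr
    a_ij <- binary_auc(score_matrix[rows, i], labels[rows] == i)
    a_ji <- binary_auc(score_matrix[rows, j], labels[rows] == j)
    (a_ij + a_ji) / 2
  }, numeric(1)))
}

# ---- classifier backends ---------------------------------------------------

#' Random-forest classifier backend
#'
#' The default accuracy backend: a seeded probability forest
#' (`ranger`, single-threaded). The backend contract is a list with
#' `fit(X, y, seed) -> model` and `score(model, X) -> per-class probability
#' matrix` (rows sum to 1), plus an `id`.
#'
#' @param num_trees number of trees.
#' @param ... further arguments passed to [ranger::ranger()].
#' @return A `classifier_backend`.
#' @export
rf_backend <- function(num_trees = 500, ...) {
  structure(list(
    id = sprintf("ranger_rf/%d", num_trees),
    fit = function(X, y, seed) {
      ranger::ranger(x = X, y = droplevels(y), probability = TRUE,
                     num.trees = num_trees, seed = seed, num.threads = 1, ...)
    },
    score = function(model, X) {
      pr <- stats::predict(model, data = X, num.threads = 1)$predictions
      pr
    }), class = "classifier_backend")
}

#' Stratified fold assignment
#'
#' Subjects are shuffled within class, ordered by class, and folds assigned
#' cyclically, so each class is spread across folds as evenly as possible and
#' overall fold sizes differ by at most one.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k), one per subject.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  ord <- withr::with_seed(seed, {
    within_class <- order(as.integer(factor(labels)),
                          stats::runif(n))
    within_class
  })
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

check_fold_classes <- function(labels, folds) {
  for (f in sort(unique(folds))) {
    present <- unique(labels[folds == f])
    if (length(present) < length(unique(labels)))
      stop("fold ", f, " is missing class(es): ",
           paste(setdiff(unique(labels), present), collapse = ", "),
           "; use fewer folds or more data")
  }
  invisible(TRUE)
}

fit_and_auc <- function(table, items, train_rows, test_rows, backend, seed) {
  Xtr <- table$data[train_rows, items, drop = FALSE]
  Xte <- table$data[test_rows, items, drop = FALSE]
  model <- backend$fit(Xtr, table$labels[train_rows], seed)
  pr <- backend$score(model, Xte)
  hand_till_auc(pr, table$labels[test_rows])
}

#' Feature-selection-aware cross-validation
#'
#' The leakage-guarding scheme: for each of `k` stratified folds, the
#' selector is run on that fold alone to produce an item set; the fold is
#' then excluded, and each remaining fold in turn serves as the test set
#' while the classifier is trained on the other `k - 2` folds restricted to
#' the selected items. The fold's AUC is the mean Hand-Till AUC over its
#' `k - 1` test folds.
#'
#' @param table a `feature_table`.
#' @param selector function(`feature_table`) returning a `selection_result`
#'   or a character vector of items.
#' @param k number of folds.
#' @param backend a `classifier_backend`.
#' @param seed RNG seed (fold assignment and model fits).
#' @return A `cv_result`: `per_fold` (data.frame with fold, n_items, auc and
#'   an `items` list-column), `overall_mean_auc`, `fold_assignment`, `seed`.
#' @export
fs_fold_cv <- function(table, selector, k = 5, backend = rf_backend(),
                       seed = 1) {
  n <- nrow(table$data)
  if (n < 5 * k) stop("need at least 5 subjects per fold")
  folds <- stratified_folds(table$labels, k, seed)
  check_fold_classes(table$labels, folds)
  fit_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, k * k), k, k))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    sel <- selector(restrict_items(table, items_of(table),
                                   rows = which(folds == f)))
    sel_items <- if (inherits(sel, "selection_result")) sel$items else sel
    if (length(sel_items) == 0) {
      warning("fold ", f, ": selector chose no items; AUC set to 0.5")
      per_fold[[f]] <- list(fold = f, items = character(0), auc = 0.5)
      next
    }
    test_folds <- setdiff(seq_len(k), f)
    aucs <- vapply(test_folds, function(t) {
      fit_and_auc(table, sel_items,
                  train_rows = which(!folds %in% c(f, t)),
                  test_rows = which(folds == t),
                  backend, fit_seeds[f, t])
    }, numeric(1))
    per_fold[[f]] <- list(fold = f, items = sel_items, auc = mean(aucs))
  }
  per_fold_df <- data.frame(
    fold = vapply(per_fold, `[[`, numeric(1), "fold"),
    n_items = vapply(per_fold, function(x) length(x$items), numeric(1)),
    auc = vapply(per_fold, `[[`, numeric(1), "auc"))
  per_fold_df$items <- lapply(per_fold, `[[`, "items")
  structure(list(per_fold = per_fold_df,
                 overall_mean_auc = mean(per_fold_df$auc),
                 fold_assignment = folds, seed = seed,
                 scheme = "fs_fold"),
            class = "cv_result")
}

#' Standard stratified k-fold AUC of a fixed item set
#'
#' Each fold in turn is the test set; the classifier is trained on the
#' remaining folds restricted to `items`, and the Hand-Till AUC on the test
#' fold is averaged over folds.
#'
#' @param table a `feature_table`.
#' @param items fixed character vector of item names.
#' @param k number of folds.
#' @param backend a `classifier_backend`.
#' @param seed RNG seed.
#' @return A `cv_result` (the same item set in every fold row).
#' @export
standard_cv_auc <- function(table, items, k = 5, backend = rf_backend(),
                            seed = 1) {
  missing <- setdiff(items, items_of(table))
  if (length(missing))
    stop("item(s) not in table: ", paste(missing, collapse = ", "))
  if (length(items) == 0) stop("empty item set")
  folds <- stratified_folds(table$labels, k, seed)
  check_fold_classes(table$labels, folds)
  fit_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, k))
  aucs <- vapply(seq_len(k), function(f) {
    fit_and_auc(table, items,
                train_rows = which(folds != f),
                test_rows = which(folds == f),
                backend, fit_seeds[f])
  }, numeric(1))
  per_fold <- data.frame(fold = seq_len(k), n_items = length(items),
                         auc = aucs)
  per_fold$items <- rep(list(items), k)
  structure(list(per_fold = per_fold, overall_mean_auc = mean(aucs),
                 fold_assignment = folds, seed = seed,
                 scheme = "standard"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$scheme, "): ", nrow(x$per_fold),
      " folds, mean AUC ", format(x$overall_mean_auc, digits = 4),
      "\n", sep = "")
  invisible(x)
}
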