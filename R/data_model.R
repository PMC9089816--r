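#' @keywords internal
"_PACKAGE"

SEVERITY_LEVELS <- c("CN", "MCI", "AD")

#' Construct a feature table
#'
#' A feature table holds one row per subject, one numeric column per
#' assessment item, a kind (`"discrete"` or `"continuous"`) for every item,
#' and a three-class dementia-severity label (`CN`, `MCI`, `AD`).
#'
#' @param data data.frame of numeric item columns (one row per subject).
#' @param labels vector of severity classes, one per subject; must only use
#'   `CN`, `MCI`, `AD`.
#' @param kinds named character vector mapping every column of `data` to
#'   `"discrete"` or `"continuous"`. If `NULL`, kinds are inferred with
#'   [infer_kind()].
#' @return An object of class `feature_table` with elements `data`, `labels`
#'   (factor with levels CN, MCI, AD) and `kinds`.
#' @export
feature_table <- function(data, labels, kinds = NULL) {
  data <- as.data.frame(data)
  if (anyDuplicated(names(data)))
    stop("duplicate column names: ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  bad <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  if (length(labels) != nrow(data))
    stop("labels length (", length(labels), ") != number of rows (", nrow(data), ")")
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), SEVERITY_LEVELS)
  if (length(unknown))
    stop("unmapped label value(s): ", paste(unknown, collapse = ", "))
  if (is.null(kinds)) {
    kinds <- vapply(data, infer_kind, character(1))
  } else {
    kinds <- kinds[names(data)]
    if (anyNA(kinds) || is.null(names(kinds)))
      stop("kinds must name every column of data")
  }
  if (!all(kinds %in% c("discrete", "continuous")))
    stop("kinds must be 'discrete' or 'continuous'")
  structure(list(data = data,
                 labels = factor(labels, levels = SEVERITY_LEVELS),
                 kinds = kinds),
            class = "feature_table")
}

#' Infer whether a numeric column is discrete or continuous
#'
#' Integer-valued vectors with at most `max_levels` distinct values are
#' treated as discrete (Likert-style assessment items); everything else is
#' continuous. The cut-off is a pragmatic default and can be overridden per
#' column through the `kinds` argument of [feature_table()].
#'
#' @param x numeric vector.
#' @param max_levels maximum number of distinct values for a discrete column.
#' @return `"discrete"` or `"continuous"`.
#' @export
infer_kind <- function(x, max_levels = 10) {
  x <- x[!is.na(x)]
  if (length(x) && all(x == round(x)) && length(unique(x)) <= max_levels)
    "discrete" else "continuous"
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$data), "subjects x", ncol(x$data), "items\n")
  cat("  kinds:", sum(x$kinds == "discrete"), "discrete,",
      sum(x$kinds == "continuous"), "continuous\n")
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Item names of a feature table
#' @param table a `feature_table`.
#' @return Character vector of item names.
#' @export
items_of <- function(table) names(table$data)

#' Restrict a feature table to a subset of its items
#' @param table a `feature_table`.
#' @param items character vector of item names to keep.
#' @param rows optional integer vector of subject rows to keep.
#' @return A `feature_table` with the requested columns (and rows).
#' @export
restrict_items <- function(table, items, rows = NULL) {
  missing <- setdiff(items, items_of(table))
  if (length(missing))
    stop("items not in table: ", paste(missing, collapse = ", "))
  if (is.null(rows)) rows <- seq_len(nrow(table$data))
  feature_table(table$data[rows, items, drop = FALSE],
                as.character(table$labels[rows]),
                kinds = table$kinds[items])
}

# ---- cost tables -----------------------------------------------------------

#' Construct an administration-time cost table
#'
#' Maps item names to estimated administration times in seconds. Items absent
#' from the table fall back to `default_cost`; the default of 1001 seconds is
#' deliberately high so that un-costed items are strongly penalised once a
#' cost weight is applied.
#'
#' @param entries named numeric vector of per-item costs (seconds, >= 0).
#' @param default_cost cost in seconds for items not in `entries`.
#' @return An object of class `cost_table`.
#' @export
cost_table <- function(entries = numeric(0), default_cost = 1001) {
  entries <- unlist(entries)
  if (length(entries) && (is.null(names(entries)) || any(names(entries) == "")))
    stop("all cost entries must be named")
  if (anyNA(entries) || !is.numeric(entries))
    stop("costs must be numeric")
  if (any(entries < 0))
    stop("negative cost for item(s): ",
         paste(names(entries)[entries < 0], collapse = ", "))
  if (!is.numeric(default_cost) || length(default_cost) != 1 || default_cost < 0)
    stop("default_cost must be a single non-negative number")
  structure(list(entries = entries, default_cost = default_cost),
            class = "cost_table")
}

#' @export
print.cost_table <- function(x, ...) {
  cat("cost_table:", length(x$entries), "items, default",
      x$default_cost, "s\n")
  invisible(x)
}

#' Look up per-item administration times
#' @param costs a `cost_table`.
#' @param items character vector of item names.
#' @return Numeric vector of costs in seconds (default cost for unknown items).
#' @export
cost_lookup <- function(costs, items) {
  out <- costs$entries[items]
  out[is.na(out)] <- costs$default_cost
  names(out) <- items
  out
}

#' Total administration time of an item set
#'
#' @param items character vector of item names (a selected subset).
#' @param costs a `cost_table`.
#' @return Total time in seconds. An empty selection returns 0 with a warning
#'   (degenerate selection).
#' @export
total_cost <- function(items, costs) {
  if (length(items) == 0) {
    warning("empty item set: total cost is 0 (degenerate selection)")
    return(0)
  }
  sum(cost_lookup(costs, items))
}

#' Built-in default cost table
#'
#' Per-item administration-time estimates (seconds) for the assessment items
#' with published time estimates: all ten FAQ items and ecog_MEMORY1 at 60 s,
#' gd_GDMEMORY 28 s, adas_Q4SCORE 600 s, adas_Q7SCORE and adas_Q8SCORE 200 s,
#' RAVLT.immediate 900 s, mmse_objects 300 s. Every other item falls back to
#' the 1001 s default.
#'
#' @return A `cost_table`.
#' @export
default_cost_table <- function() {
  faq <- paste0("faq_", c("FAQFINAN", "FAQFORM", "FAQSHOP", "FAQGAME",
                          "FAQBEVG", "FAQMEAL", "FAQEVENT", "FAQTV",
                          "FAQREM", "FAQTRAVL"))
  entries <- c(stats::setNames(rep(60, length(faq)), faq),
               ecog_MEMORY1 = 60, gd_GDMEMORY = 28,
               adas_Q4SCORE = 600, adas_Q7SCORE = 200, adas_Q8SCORE = 200,
               RAVLT.immediate = 900, mmse_objects = 300)
  cost_table(entries, default_cost = 1001)
}

# ---- severity recoding -----------------------------------------------------

#' Construct a CDR-SB severity recoder
#'
#' CDR-SB (Clinical Dementia Rating Sum-of-Boxes, 0-18 in 0.5 steps) is first
#' mapped to a five-level stage by upper-bound thresholds, then the stages are
#' grouped into the three analysis classes; the mild, moderate and severe
#' dementia stages are amalgamated into AD.
#'
#' @param stage_thresholds named numeric vector: upper bound (inclusive) of
#'   each stage, strictly increasing, last bound 18.
#' @param group_map named character vector mapping each stage to CN/MCI/AD.
#' @return An object of class `severity_recoder`.
#' @export
severity_recoder <- function(
    stage_thresholds = c(normal = 0, questionable = 4, mild = 9,
                         moderate = 15.5, severe = 18),
    group_map = c(normal = "CN", questionable = "MCI", mild = "AD",
                  moderate = "AD", severe = "AD")) {
  if (is.unsorted(stage_thresholds, strictly = TRUE))
    stop("stage thresholds must be strictly increasing")
  if (!setequal(names(stage_thresholds), names(group_map)))
    stop("group_map must map exactly the stages named in stage_thresholds")
  if (!all(group_map %in% SEVERITY_LEVELS))
    stop("group_map values must be CN, MCI or AD")
  structure(list(stage_thresholds = stage_thresholds,
                 group_map = group_map[names(stage_thresholds)]),
            class = "severity_recoder")
}

#' Recode CDR-SB scores to CN/MCI/AD
#'
#' @param score numeric vector of CDR-SB values in `[0, 18]`, multiples of 0.5.
#' @param recoder a [severity_recoder()]; the default places 0 in CN,
#'   0.5-4.0 in MCI and everything above in AD.
#' @return Character vector of severity classes.
#' @export
recode_cdrsb <- function(score, recoder = severity_recoder()) {
  bad <- !is.finite(score) | score < 0 | score > 18 |
    abs(score * 2 - round(score * 2)) > 1e-9
  if (any(bad))
    stop("CDR-SB score(s) out of range [0, 18] or not a multiple of 0.5: ",
         paste(utils::head(score[bad], 5), collapse = ", "))
  stage_idx <- findInterval(score, recoder$stage_thresholds,
                            left.open = TRUE) + 1L
  unname(recoder$group_map[stage_idx])
}

# ---- file I/O --------------------------------------------------------------

#' Load a feature table from CSV
#'
#' Reads a header-rowed CSV with one row per subject. The label column may
#' hold either CN/MCI/AD classes or raw CDR-SB scores (`cdrsb = TRUE`), in
#' which case it is recoded. Rows with a missing label are dropped (with a
#' message counting them). Remaining missing feature values are handled by
#' complete-case analysis by default, or by median (continuous) / mode
#' (discrete) imputation with `impute = TRUE`.
#'
#' @param path CSV file path.
#' @param label_column name of the label column.
#' @param kind_hints optional named character vector of per-column kinds.
#' @param cdrsb if `TRUE`, treat the label column as raw CDR-SB and recode.
#' @param recoder recoder used when `cdrsb = TRUE`.
#' @param impute impute missing feature values instead of dropping rows.
#' @return A `feature_table`.
#' @export
load_feature_table <- function(path, label_column, kind_hints = NULL,
                               cdrsb = FALSE, recoder = severity_recoder(),
                               impute = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(raw)))
    stop("duplicate column names in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  if (!label_column %in% names(raw))
    stop("label column '", label_column, "' not found in ", path)
  lab_raw <- raw[[label_column]]
  keep <- !is.na(lab_raw) & lab_raw != ""
  if (sum(!keep))
    message("dropped ", sum(!keep), " row(s) with missing label")
  raw <- raw[keep, , drop = FALSE]
  lab_raw <- lab_raw[keep]
  labels <- if (cdrsb) recode_cdrsb(as.numeric(lab_raw), recoder)
            else as.character(lab_raw)
  data <- raw[, setdiff(names(raw), label_column), drop = FALSE]
  for (nm in names(data)) {
    if (!is.numeric(data[[nm]])) {
      conv <- suppressWarnings(as.numeric(data[[nm]]))
      introduced <- is.na(conv) & !is.na(data[[nm]]) & data[[nm]] != ""
      if (any(introduced))
        stop("non-numeric value in column '", nm, "', row ",
             which(introduced)[1])
      data[[nm]] <- conv
    }
  }
  if (anyNA(data)) {
    if (impute) {
      for (nm in names(data)) {
        v <- data[[nm]]
        if (!anyNA(v)) next
        kind <- if (!is.null(kind_hints) && nm %in% names(kind_hints))
          kind_hints[[nm]] else infer_kind(v)
        fill <- if (kind == "discrete") {
          tab <- table(v)
          as.numeric(names(tab)[which.max(tab)])
        } else stats::median(v, na.rm = TRUE)
        v[is.na(v)] <- fill
        data[[nm]] <- v
      }
    } else {
      cc <- stats::complete.cases(data)
      message("dropped ", sum(!cc), " incomplete row(s) (complete-case)")
      data <- data[cc, , drop = FALSE]
      labels <- labels[cc]
    }
  }
  feature_table(data, labels, kinds = kind_hints)
}

#' Write a feature table to CSV
#'
#' The inverse of [load_feature_table()]: the label is stored in
#' `label_column` and a sidecar `<path>.kinds.csv` records per-column kinds so
#' a round-trip reproduces the table exactly.
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @param label_column label column name to use.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, label_column = "severity") {
  out <- table$data
  out[[label_column]] <- as.character(table$labels)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(column = names(table$kinds),
                              kind = unname(table$kinds)),
                   paste0(path, ".kinds.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a cost table from CSV
#'
#' Expects two columns, `item` and `cost_seconds` (header optional names; the
#' first two columns are used). Items absent from the file fall back to
#' `default_cost`.
#'
#' @param path CSV file path.
#' @param default_cost default for unknown items, seconds.
#' @return A `cost_table`.
#' @export
load_cost_table <- function(path, default_cost = 1001) {
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0)
    return(cost_table(numeric(0), default_cost = default_cost))
  if (ncol(raw) < 2)
    stop("cost table needs two columns (item, cost_seconds): ", path)
  item <- as.character(raw[[1]])
  cost <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(cost))
    stop("non-numeric cost in row(s): ",
         paste(which(is.na(cost)), collapse = ", "))
  if (any(cost < 0))
    stop("negative cost in row(s): ", paste(which(cost < 0), collapse = ", "))
  cost_table(stats::setNames(cost, item), default_cost = default_cost)
}

#' Write a cost table to CSV
#' @param costs a `cost_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(costs, path) {
  utils::write.csv(data.frame(item = names(costs$entries),
                              cost_seconds = unname(costs$entries)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
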