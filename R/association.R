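#' Equal-frequency discretization
#'
#' Bins a continuous vector at its empirical quantiles. Equal values always
#' land in the same bin; a constant vector collapses to a single bin with a
#' warning. Bin labels run from 0 to `n_bins - 1` (fewer when ties merge
#' boundaries).
#'
#' @param values numeric vector, length >= `n_bins`.
#' @param n_bins number of bins, >= 2.
#' @param method only `"equal_frequency"` is implemented.
#' @return Integer vector of bin labels.
#' @export
discretize <- function(values, n_bins = 5, method = "equal_frequency") {
  method <- match.arg(method, "equal_frequency")
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(values) < n_bins)
    stop("vector shorter than n_bins")
  if (length(unique(values)) == 1) {
    warning("constant vector: single bin")
    return(rep(0L, length(values)))
  }
  qs <- unique(stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                               names = FALSE))
  findInterval(values, qs, left.open = TRUE)
}

entropy_nats <- function(x) {
  p <- table(x)
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

#' Plug-in mutual information (nats)
#'
#' \eqn{\sum_{a,b} p(a,b)\,\ln[p(a,b)/(p(a)p(b))]} over the empirical joint
#' distribution, with the convention \eqn{0 \ln 0 = 0}.
#'
#' @param x,y discrete vectors of equal length.
#' @return Mutual information in nats, >= 0 up to floating error.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  ratio <- joint / outer(px, py)
  max(0, sum(joint * log(ratio), na.rm = TRUE))
}

#' Absolute Pearson correlation
#'
#' @param a,b numeric vectors of equal length (>= 3). A constant input yields
#'   0 with a warning (correlation undefined).
#' @return Value in `[0, 1]`.
#' @export
pearson_abs <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input: correlation undefined, returning 0")
    return(0)
  }
  abs(stats::cor(a, b))
}

#' Symmetrical uncertainty
#'
#' The entropy-normalized mutual information `2 MI / (H(x) + H(y))`, bounded
#' in `[0, 1]`; 0 when both entropies vanish. Puts discrete-discrete
#' associations on the same scale as a squared-correlation-like quantity.
#'
#' @param x,y discrete vectors of equal length.
#' @return Value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy_nats(x); hy <- entropy_nats(y)
  if (hx + hy == 0) return(0)
  min(1, 2 * mutual_information(x, y) / (hx + hy))
}

#' Precompute feature-class and feature-feature associations
#'
#' Builds the correlation cache feeding the merit heuristic. In the default
#' `"fselector"` mode, discrete-discrete pairs (and every pair involving the
#' class) use raw mutual information while continuous-continuous pairs use
#' absolute Pearson correlation; this mixes scales (nats vs `[0, 1]`
#' correlation), which can suppress continuous items whenever their mutual
#' correlations are numerically large relative to MI-scale class
#' associations. The `"symmetrical_uncertainty"` mode is fully
#' scale-consistent in the spirit of Hall's original CFS: every association,
#' including continuous-continuous, is SU on `[0, 1]` after discretization.
#' Continuous vectors entering an MI/SU computation are first discretized
#' into 5 equal-frequency bins.
#'
#' @param table a `feature_table`.
#' @param mode `"fselector"` or `"symmetrical_uncertainty"`.
#' @param n_bins bins for discretizing continuous items.
#' @return An object of class `correlation_cache` with `feature_class` (named
#'   vector) and `feature_feature` (symmetric matrix).
#' @export
build_correlation_cache <- function(table,
                                    mode = c("fselector",
                                             "symmetrical_uncertainty"),
                                    n_bins = 5) {
  mode <- match.arg(mode)
  disc_measure <- if (mode == "fselector") mutual_information
                  else symmetrical_uncertainty
  items <- items_of(table)
  p <- length(items)
  disc <- lapply(items, function(nm) {
    v <- table$data[[nm]]
    if (table$kinds[[nm]] == "continuous")
      suppressWarnings(discretize(v, n_bins)) else v
  })
  names(disc) <- items
  lab <- table$labels

  fc <- vapply(items, function(nm) disc_measure(disc[[nm]], lab), numeric(1))

  ff <- matrix(0, p, p, dimnames = list(items, items))
  if (p > 1) {
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        a <- items[i]; b <- items[j]
        v <- if (mode == "fselector" &&
                 table$kinds[[a]] == "continuous" &&
                 table$kinds[[b]] == "continuous")
          suppressWarnings(pearson_abs(table$data[[a]], table$data[[b]]))
        else disc_measure(disc[[a]], disc[[b]])
        ff[i, j] <- ff[j, i] <- v
      }
    }
  }
  diag(ff) <- vapply(items, function(nm) {
    if (mode == "fselector") entropy_nats(disc[[nm]])
    else if (entropy_nats(disc[[nm]]) > 0) 1 else 0
  }, numeric(1))
  structure(list(feature_class = fc, feature_feature = ff,
                 mode = mode, items = items),
            class = "correlation_cache")
}

#' @export
print.correlation_cache <- function(x, ...) {
  cat("correlation_cache (", x$mode, "): ", length(x$items), " items\n",
      sep = "")
  invisible(x)
}

#' Serialize a correlation cache to CSV for inspection
#' @param cache a `correlation_cache`.
#' @param path output CSV path (long format: item_a, item_b, value; the class
#'   appears as item_b = ".class").
#' @return `path`, invisibly.
#' @export
write_correlation_cache <- function(cache, path) {
  idx <- which(upper.tri(cache$feature_feature, diag = FALSE), arr.ind = TRUE)
  long <- rbind(
    data.frame(item_a = cache$items, item_b = ".class",
               value = unname(cache$feature_class)),
    data.frame(item_a = cache$items[idx[, 1]],
               item_b = cache$items[idx[, 2]],
               value = cache$feature_feature[idx]))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
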