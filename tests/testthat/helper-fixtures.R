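# Small in-code fixtures shared across tests.

# A tiny deterministic table: one discrete item that mirrors the class, one
# continuous item, one discrete noise item.
tiny_table <- function(n_per_class = 10) {
  labels <- rep(c("CN", "MCI", "AD"), each = n_per_class)
  cls <- rep(0:2, each = n_per_class)
  set.seed(99)
  feature_table(
    data.frame(mirror = cls,
               cont = cls + rnorm(3 * n_per_class, sd = 0.3),
               junk = rep_len(c(0, 1), 3 * n_per_class)),
    labels)
}

# Random small table for brute-force comparisons.
random_small_table <- function(seed, n = 40, p = 4, levels = 3) {
  set.seed(seed)
  data <- as.data.frame(matrix(sample.int(levels, n * p, replace = TRUE),
                               n, p))
  names(data) <- paste0("it", seq_len(p))
  feature_table(data, sample(c("CN", "MCI", "AD"), n, replace = TRUE))
}

# A hand-made correlation cache (for merit formula checks).
manual_cache <- function(fc, ff) {
  items <- names(fc)
  structure(list(feature_class = fc,
                 feature_feature = ff,
                 mode = "manual", items = items),
            class = "correlation_cache")
}

uniform_cache <- function(items, rcf, rff) {
  p <- length(items)
  ff <- matrix(rff, p, p, dimnames = list(items, items))
  diag(ff) <- 1
  manual_cache(stats::setNames(rep(rcf, p), items), ff)
}

# Independent brute-force Hand-Till AUC: enumerate all cross-class row pairs.
brute_hand_till <- function(score_matrix, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  pair_auc <- function(i, j) {
    si <- score_matrix[labels == i, i]
    sj <- score_matrix[labels == j, i]
    tot <- 0
    for (a in si) for (b in sj)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(si) * length(sj))
  }
  vals <- utils::combn(classes, 2, function(pr) {
    (pair_auc(pr[1], pr[2]) + pair_auc(pr[2], pr[1])) / 2
  })
  mean(vals)
}

# Independent brute-force inconsistency rate.
brute_inconsistency <- function(table, subset) {
  cols <- lapply(subset, function(nm) {
    v <- table$data[[nm]]
    if (table$kinds[[nm]] == "continuous")
      suppressWarnings(cfaopt::discretize(v, 5)) else v
  })
  key <- do.call(paste, c(cols, sep = "|"))
  total <- 0
  for (k in unique(key)) {
    labs <- table$labels[key == k]
    total <- total + length(labs) - max(base::table(labs))
  }
  total / nrow(table$data)
}

# Fast classifier backend for unit tests: per-class mean profile scoring
# (nearest-centroid softmax). Deterministic and cheap.
centroid_backend <- function() {
  structure(list(
    id = "centroid",
    fit = function(X, y, seed) {
      list(centers = lapply(split(as.data.frame(X), y), colMeans),
           classes = levels(droplevels(y)))
    },
    score = function(model, X) {
      d <- vapply(model$centers, function(ct)
        rowSums(sweep(as.matrix(X), 2, ct)^2), numeric(nrow(X)))
      if (is.null(dim(d))) d <- matrix(d, nrow = 1,
                                       dimnames = list(NULL, names(model$centers)))
      w <- exp(-d)
      w / pmax(rowSums(w), 1e-300)
    }), class = "classifier_backend")
}
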