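#' Synthetic assessment-data specification
#'
#' Defines a generator for labelled subject-by-item tables that emulate the
#' structure of a cognitive/functional assessment battery: a 3-class severity
#' label, informative continuous and ordinal items whose distributions shift
#' with severity, redundant near-copies of informative items, class-independent
#' noise items of both kinds, and per-item administration-time costs.
#'
#' Informative continuous items are class-conditional Gaussians with means
#' 0, d, 2d (unit variance) for CN, MCI, AD, where d = `effect_size`.
#' Informative ordinal items threshold the same kind of shifted latent
#' Gaussian into `discrete_levels` equal-frequency levels, mirroring
#' Likert-style items. Redundant items are a parent plus Gaussian noise scaled
#' to reach `redundancy_corr`, re-discretized when the parent is ordinal.
#'
#' @param n_subjects number of subjects.
#' @param class_probs length-3 probability vector for CN, MCI, AD.
#' @param n_informative_continuous,n_informative_discrete,n_redundant,n_noise
#'   item counts per role; noise items are split between both kinds.
#' @param effect_size standardized between-adjacent-class mean separation
#'   (Cohen's-d-like) of informative items.
#' @param redundancy_corr target correlation of redundant copies with their
#'   parents, in `[0, 1]`.
#' @param discrete_levels number of ordinal levels for discrete items.
#' @param cost_rule either a named numeric vector of per-role costs
#'   (`informative`, `redundant`, `noise`, seconds) or `NULL` to draw each
#'   item's cost from the published time scale \{28, 60, 200, 300, 600, 900\}.
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 600,
                           class_probs = c(1, 1, 1) / 3,
                           n_informative_continuous = 5,
                           n_informative_discrete = 3,
                           n_redundant = 4,
                           n_noise = 40,
                           effect_size = 1.2,
                           redundancy_corr = 0.9,
                           discrete_levels = 4,
                           cost_rule = NULL,
                           seed = 1) {
  if (length(class_probs) != 3 || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must be 3 non-negative values summing to 1")
  counts <- c(n_subjects, n_informative_continuous, n_informative_discrete,
              n_redundant, n_noise)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (redundancy_corr < 0 || redundancy_corr > 1)
    stop("redundancy_corr must be in [0, 1]")
  if (n_redundant > 0 && n_informative_continuous + n_informative_discrete == 0)
    stop("redundant items need at least one informative parent")
  structure(list(n_subjects = n_subjects, class_probs = class_probs,
                 n_informative_continuous = n_informative_continuous,
                 n_informative_discrete = n_informative_discrete,
                 n_redundant = n_redundant, n_noise = n_noise,
                 effect_size = effect_size,
                 redundancy_corr = redundancy_corr,
                 discrete_levels = discrete_levels,
                 cost_rule = cost_rule, seed = as.integer(seed)),
            class = "synthetic_spec")
}

latent_to_ordinal <- function(latent, levels) {
  qs <- stats::quantile(latent, probs = seq_len(levels - 1) / levels,
                        names = FALSE)
  findInterval(latent, unique(qs))
}

#' Generate a synthetic labelled assessment table
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `table` (a `feature_table`), `costs` (a
#'   `cost_table`) and `truth` (data.frame with columns `item`, `role`,
#'   `parent`; role is `informative`, `redundant` or `noise`).
#' @export
generate_assessment_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_subjects
    d <- spec$effect_size
    cls <- sample.int(3, n, replace = TRUE, prob = spec$class_probs)
    labels <- SEVERITY_LEVELS[cls]
    shift <- (cls - 1) * d

    cols <- list(); kinds <- character(0)
    truth <- data.frame(item = character(0), role = character(0),
                        parent = character(0), stringsAsFactors = FALSE)
    add <- function(name, values, kind, role, parent = NA_character_) {
      cols[[name]] <<- values
      kinds[name] <<- kind
      truth[nrow(truth) + 1L, ] <<- list(name, role, parent)
    }

    for (i in seq_len(spec$n_informative_continuous))
      add(sprintf("inf_cont_%02d", i), shift + stats::rnorm(n),
          "continuous", "informative")
    for (i in seq_len(spec$n_informative_discrete))
      add(sprintf("inf_ord_%02d", i),
          latent_to_ordinal(shift + stats::rnorm(n), spec$discrete_levels),
          "discrete", "informative")

    parents <- truth$item[truth$role == "informative"]
    if (spec$n_redundant > 0) {
      r <- spec$redundancy_corr
      for (i in seq_len(spec$n_redundant)) {
        parent <- parents[((i - 1) %% length(parents)) + 1]
        pv <- cols[[parent]]
        noise_sd <- if (r > 0) stats::sd(pv) * sqrt(1 / r^2 - 1) else Inf
        child <- if (is.finite(noise_sd)) pv + stats::rnorm(n, sd = noise_sd)
                 else stats::rnorm(n)
        if (kinds[parent] == "discrete") {
          add(sprintf("red_%02d", i),
              latent_to_ordinal(child, spec$discrete_levels),
              "discrete", "redundant", parent)
        } else {
          add(sprintf("red_%02d", i), child, "continuous", "redundant", parent)
        }
      }
    }

    n_noise_cont <- ceiling(spec$n_noise / 2)
    for (i in seq_len(spec$n_noise)) {
      if (i <= n_noise_cont) {
        add(sprintf("noise_cont_%02d", i), stats::rnorm(n),
            "continuous", "noise")
      } else {
        add(sprintf("noise_ord_%02d", i - n_noise_cont),
            latent_to_ordinal(stats::rnorm(n), spec$discrete_levels),
            "discrete", "noise")
      }
    }

    tab <- feature_table(as.data.frame(cols, check.names = FALSE),
                         labels, kinds = kinds)
    scale <- c(28, 60, 200, 300, 600, 900)
    cost_of <- function(role) {
      if (is.null(spec$cost_rule)) sample(scale, 1)
      else unname(spec$cost_rule[[role]])
    }
    cost_entries <- vapply(seq_len(nrow(truth)),
                           function(i) cost_of(truth$role[i]), numeric(1))
    names(cost_entries) <- truth$item
    list(table = tab, costs = cost_table(cost_entries), truth = truth)
  })
}

#' Twin-item scenario for cost-sensitivity checks
#'
#' Builds a table in which one informative signal exists only as two
#' near-identical copies (sample correlation at least 0.95): `twin_cheap`
#' priced at `cheap_cost` seconds and `twin_dear` at `dear_cost`. A plain CFS
#' cannot distinguish the twins by accuracy, so any systematic preference for
#' the cheap one must come from the cost penalty. All other items are also
#' priced at `cheap_cost`, so the twins' time difference is the only cost
#' signal in the table: the mean-cost penalty is constant across equally
#' priced subsets and the cost-sensitive search differs from plain CFS only
#' in which twin it keeps.
#'
#' @param base_spec a [synthetic_spec()] with at least one informative
#'   continuous item.
#' @param cheap_cost,dear_cost the twins' administration times, seconds.
#' @return As [generate_assessment_data()]; the truth table marks both twins.
#' @export
duplicate_item_scenario <- function(base_spec, cheap_cost = 60,
                                    dear_cost = 900) {
  if (base_spec$n_informative_continuous < 1)
    stop("base_spec needs at least one informative continuous item")
  gen <- generate_assessment_data(base_spec)
  parent <- gen$truth$item[gen$truth$role == "informative" &
                           gen$table$kinds[gen$truth$item] == "continuous"][1]
  signal <- gen$table$data[[parent]]
  # correlation of each twin with the latent signal ~0.985 -> twin-twin >= 0.95
  twin_sd <- stats::sd(signal) * sqrt(1 / 0.985^2 - 1)
  withr::with_seed(base_spec$seed + 1L, {
    twin_a <- signal + stats::rnorm(length(signal), sd = twin_sd)
    twin_b <- signal + stats::rnorm(length(signal), sd = twin_sd)
  })
  data <- gen$table$data
  data[[parent]] <- NULL
  data[["twin_cheap"]] <- twin_a
  data[["twin_dear"]] <- twin_b
  kinds <- gen$table$kinds[names(gen$table$kinds) != parent]
  kinds <- c(kinds, twin_cheap = "continuous", twin_dear = "continuous")
  tab <- feature_table(data, as.character(gen$table$labels), kinds = kinds)
  others <- setdiff(names(gen$costs$entries), parent)
  entries <- c(stats::setNames(rep(cheap_cost, length(others)), others),
               twin_cheap = cheap_cost, twin_dear = dear_cost)
  truth <- gen$truth[gen$truth$item != parent, ]
  truth <- rbind(truth,
                 data.frame(item = c("twin_cheap", "twin_dear"),
                            role = "informative", parent = NA_character_))
  list(table = tab, costs = cost_table(entries), truth = truth)
}
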