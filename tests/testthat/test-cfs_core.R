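test_that("merit reproduces hand-evaluated cases", {
  cache <- uniform_cache(c("a", "b", "c"), rcf = 0.4, rff = 0.2)
  expect_equal(merit(c("a", "b", "c"), cache), 1.2 / sqrt(4.2),
               tolerance = 1e-12)
  single <- manual_cache(c(a = 0.5), matrix(1, 1, 1,
                                            dimnames = list("a", "a")))
  expect_equal(merit("a", single), 0.5, tolerance = 1e-12)
  zero <- uniform_cache(c("a", "b"), rcf = 0, rff = 0.3)
  expect_equal(merit(c("a", "b"), zero), 0, tolerance = 1e-12)
})

test_that("merit rejects empty subsets and unknown items", {
  cache <- uniform_cache(c("a", "b"), 0.4, 0.1)
  expect_error(merit(character(0), cache), "empty")
  expect_error(merit(c("a", "zz"), cache), "zz")
})

test_that("merit is invariant to subset order and row permutation", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 100, n_noise = 4,
                                               seed = 17))
  cache <- build_correlation_cache(g$table)
  set.seed(3)
  for (i in 1:20) {
    s <- sample(items_of(g$table), sample(2:5, 1))
    expect_equal(merit(s, cache), merit(rev(s), cache), tolerance = 1e-12)
    expect_equal(merit(s, cache), merit(sample(s), cache), tolerance = 1e-12)
  }
})

test_that("cost merit subtracts the mean time penalty", {
  cache <- uniform_cache(c("a", "b", "c"), rcf = 0.4, rff = 0.2)
  costs <- cost_table(c(a = 60, b = 60, c = 120))
  p <- merit_params(0.001, costs)
  expect_equal(cost_merit(c("a", "b", "c"), cache, p),
               1.2 / sqrt(4.2) - 0.001 * 240 / 3, tolerance = 1e-12)
  # linear in lambda: doubling lambda doubles the subtracted term
  p2 <- merit_params(0.002, costs)
  m <- merit(c("a", "b", "c"), cache)
  expect_equal(m - cost_merit(c("a", "b", "c"), cache, p2),
               2 * (m - cost_merit(c("a", "b", "c"), cache, p)),
               tolerance = 1e-12)
})

test_that("zero cost weight recovers plain merit on random subsets", {
  for (seed in c(23, 24)) {
    g <- generate_assessment_data(synthetic_spec(n_subjects = 100,
                                                 n_noise = 6, seed = seed))
    cache <- build_correlation_cache(g$table)
    p0 <- merit_params(0, cost_table(c(x = 100)))
    set.seed(seed)
    for (i in 1:100) {
      s <- sample(items_of(g$table), sample(seq_along(items_of(g$table)), 1))
      expect_identical(cost_merit(s, cache, p0), merit(s, cache))
    }
  }
})

test_that("best-first search handles a single-item pool", {
  res <- best_first_search(function(s) 0.7, "only")
  expect_equal(res$items, "only")
  expect_equal(res$score, 0.7)
})

test_that("best-first attains the exhaustive optimum on small pools", {
  for (s in 1:20) {
    g <- generate_assessment_data(synthetic_spec(
      n_subjects = 120, n_informative_continuous = 2,
      n_informative_discrete = 2, n_redundant = 2, n_noise = 2, seed = s))
    cache <- build_correlation_cache(g$table,
                                     mode = "symmetrical_uncertainty")
    ev <- function(su) merit(su, cache)
    bf <- best_first_search(ev, items_of(g$table))
    ex <- exhaustive_search(ev, items_of(g$table))
    expect_equal(bf$score, ex$score, tolerance = 1e-9)
  }
})

test_that("best-first score is pool-order invariant and beats singletons", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 150, n_noise = 4,
                                               seed = 33))
  cache <- build_correlation_cache(g$table)
  ev <- function(su) merit(su, cache)
  pool <- items_of(g$table)
  r1 <- best_first_search(ev, pool)
  set.seed(1)
  r2 <- best_first_search(ev, sample(pool))
  expect_equal(r1$score, r2$score, tolerance = 1e-9)
  expect_true(all(r1$score >= cache$feature_class[pool] - 1e-12))
  # the returned score re-evaluates at the returned items
  expect_equal(r1$score, ev(r1$items), tolerance = 1e-12)
})

test_that("exhaustive search enumerates and breaks ties lexicographically", {
  vals <- c(a = 0.5, b = 0.1, ab = 0.4)
  ev <- function(s) vals[[paste(sort(s), collapse = "")]]
  ex <- exhaustive_search(ev, c("a", "b"))
  expect_equal(ex$items, "a")
  expect_equal(ex$score, 0.5)
  expect_equal(exhaustive_search(function(s) 1, "solo")$items, "solo")
  # all-tied scores: the lexicographically smallest subset wins
  tied <- exhaustive_search(function(s) 0.5, c("b", "a", "c"))
  expect_equal(tied$items, "a")
  expect_error(exhaustive_search(function(s) 1, paste0("i", 1:21)), "20")
})

test_that("CFS prefers a label-mirroring item over redundant copies", {
  labels <- rep(c("CN", "MCI", "AD"), each = 12)
  cls <- rep(0:2, each = 12)
  set.seed(8)
  tab <- feature_table(
    data.frame(mirror = cls, copy = cls,
               weak = cls + rnorm(36, sd = 2),
               junk = rep_len(c(1, 0), 36)),
    labels)
  res <- cfs_select(tab)
  expect_true("mirror" %in% res$items || "copy" %in% res$items)
  expect_false(all(c("mirror", "copy") %in% res$items))
  expect_false("junk" %in% res$items)
})

test_that("a null-signal table yields near-zero selected merit", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 1000,
                                               effect_size = 0, n_noise = 10,
                                               seed = 19))
  res <- cfs_select(g$table)
  expect_lt(res$score, 0.05)
})

test_that("cost-sensitive CFS at lambda 0 matches plain CFS", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 200, n_noise = 8,
                                               seed = 29))
  plain <- cfs_select(g$table)
  zero <- cost_cfs_select(g$table, merit_params(0, g$costs))
  expect_equal(zero$score, plain$score, tolerance = 1e-12)
  expect_equal(zero$items, plain$items)
})

test_that("a strong cost weight never raises the selected total time", {
  for (s in 1:5) {
    g <- generate_assessment_data(synthetic_spec(n_subjects = 200,
                                                 n_noise = 8, seed = s))
    at0 <- cost_cfs_select(g$table, merit_params(0, g$costs))
    big <- cost_cfs_select(g$table, merit_params(10, g$costs))
    expect_lte(total_cost(big$items, g$costs), total_cost(at0$items, g$costs))
  }
})
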